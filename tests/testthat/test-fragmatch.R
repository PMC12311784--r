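test_that("fragment matching assigns each peak to its nearest fragment", {
  p <- proteoform("AG")
  lad <- fragment_ladder(p, c("c", "zdot"))
  pk <- spectrum_peaks(lad$neutral_mass, rep(100, nrow(lad)), "neutral")
  m <- match_fragments(p, pk, c("c", "zdot"))
  expect_equal(nrow(m), 2)
  expect_equal(m$error_ppm, c(0, 0))
  # +5 ppm jitter still matches at 10 ppm, with ~5 ppm reported error
  pk5 <- spectrum_peaks(lad$neutral_mass * (1 + 5e-6), rep(100, nrow(lad)),
                        "neutral")
  m5 <- match_fragments(p, pk5, c("c", "zdot"))
  expect_equal(nrow(m5), 2)
  expect_equal(m5$error_ppm, c(5, 5), tolerance = 1e-6)
  # a peak midway between fragments 50 ppm apart matches neither at 10 ppm
  mid <- spectrum_peaks(88.06366 * (1 + 25e-6), 10, "neutral")
  expect_equal(nrow(match_fragments(p, mid, "c", tol_ppm = 10)), 0)
  expect_equal(nrow(match_fragments(p, spectrum_peaks(numeric(0), numeric(0)),
                                    c("c", "zdot"))), 0)
})

test_that("m/z mode enumerates charges with deterministic tie-breaks", {
  p <- parse_proteoform("N-propG K6prop", "GSTGGKAPR")
  lad <- fragment_ladder(p, c("b", "y"))
  mz2 <- mz_from_mass(lad$neutral_mass, 2)
  pk <- spectrum_peaks(mz2, rep(50, length(mz2)), "mz")
  m <- match_fragments(p, pk, c("b", "y"), max_charge = 2)
  expect_true(all(m$charge %in% 1:2))
  expect_equal(nrow(m), nrow(pk))
})

test_that("sequence coverage follows the flanking-cleavage definition", {
  expect_equal(sequence_coverage(matches_from_cleavages(1:3, 10), 10), 30)
  expect_equal(sequence_coverage(matches_from_cleavages(1:9, 10), 10), 100)
  expect_equal(sequence_coverage(matches_from_cleavages(integer(0), 10), 10), 0)
  # n = 1: both termini evidenced, the single residue is confirmed
  expect_equal(sequence_coverage(matches_from_cleavages(integer(0), 1), 1), 100)
  # against the per-definition oracle on random cleavage sets
  set.seed(13)
  for (rep in 1:50) {
    n <- sample(2:60, 1)
    cl <- sort(sample(seq_len(n - 1), sample(0:(n - 1), 1)))
    expect_equal(sequence_coverage(matches_from_cleavages(cl, n), n),
                 oracle_sc_from_cleavages(cl, n))
  }
})

test_that("sequence validation counts disjoint terminal runs", {
  # confirmed {1,2,3} from N plus {9,10} from C: (3+2)/10
  m <- rbind(matches_from_cleavages(1:3, 10),
             within(matches_from_cleavages(8:9, 10), series <- "y"))
  m$series <- c("c", "c", "c", "y", "y")
  m$index <- c(1L, 2L, 3L, 2L, 1L)
  expect_equal(sequence_validation(m, 10), 50)
  expect_equal(sequence_coverage(m, 10), 50)
  expect_equal(sequence_validation(matches_from_cleavages(1:9, 10), 10), 100)
  # interior-only confirmation contributes nothing
  expect_equal(sequence_validation(matches_from_cleavages(4:5, 10), 10), 0)
  expect_equal(sequence_coverage(matches_from_cleavages(4:5, 10), 10), 10)
})

test_that("intensity coverage never double-counts peaks", {
  p <- proteoform("AGSK")
  lad <- fragment_ladder(p, c("c", "zdot"))
  pk <- spectrum_peaks(c(lad$neutral_mass[1], 500, 900),
                       c(400, 350, 250), "neutral")
  m <- match_fragments(p, pk, c("c", "zdot"))
  expect_equal(intensity_coverage(m, pk), 40)
  full <- spectrum_peaks(lad$neutral_mass, rep(1, nrow(lad)), "neutral")
  expect_equal(intensity_coverage(match_fragments(p, full, c("c", "zdot")),
                                  full), 100)
  # adversarial: c and zdot of a symmetric peptide can collide on one
  # peak; the one-to-one rule keeps IC <= 100
  expect_lte(intensity_coverage(m, pk), 100)
  empty <- spectrum_peaks(1000, 0, "neutral")
  expect_error(intensity_coverage(m, empty), class = "hf_zero_intensity")
})

test_that("MS score is the Eq-style product on a 0-100 scale", {
  expect_equal(ms_score(100, 100), 100)
  expect_equal(ms_score(50, 50), 25)
  # the H2A N-acS printed inputs: the product formula gives 60.995 /
  # 35.736 where the source prints 59.94 / 34.45 (vendor-side rounding
  # unknown; the formula is applied literally)
  expect_equal(ms_score(92.74, 65.77), 60.9951, tolerance = 1e-6)
  expect_equal(ms_score(89.52, 39.92), 35.7364, tolerance = 1e-6)
  expect_error(ms_score(120, 50), class = "hf_bad_arg")
})

test_that("score_proteoform composes the four metrics", {
  p <- parse_proteoform("N-acS K16ac", h4_toy)
  lad <- fragment_ladder(p, c("c", "zdot", "a"))
  pk <- spectrum_peaks(lad$neutral_mass, rep(100, nrow(lad)), "neutral")
  r <- score_proteoform(p, pk)
  expect_equal(r$sc_pct, 100)
  expect_equal(r$svp_pct, 100)
  expect_equal(r$ic_pct, 100)
  expect_equal(r$ms, 100)
  # the wrong positional isomer scores strictly lower on the same spectrum
  wrong <- parse_proteoform("N-acS K12ac", h4_toy)
  rw <- score_proteoform(wrong, pk)
  expect_lt(rw$ms, r$ms)
  # empty spectrum: all-zero scores
  r0 <- score_proteoform(p, spectrum_peaks(numeric(0), numeric(0)))
  expect_equal(c(r0$sc_pct, r0$svp_pct, r0$ic_pct, r0$ms), c(0, 0, 0, 0))
})

test_that("score invariants hold on random fixtures", {
  set.seed(17)
  for (rep in 1:60) {
    p <- random_proteoform(n = sample(6:25, 1))
    cfg <- sim_config(seed = rep, completeness = stats::runif(1),
                      ppm_jitter = stats::runif(1, 0, 5),
                      noise_fraction = stats::runif(1, 0, 0.3))
    sim <- simulate_ecd_spectrum(p, cfg)
    r <- score_proteoform(p, sim$peaks)
    expect_gte(r$sc_pct, r$svp_pct)
    expect_lte(r$ms, min(r$sc_pct, r$ic_pct) + 1e-9)
    expect_true(all(c(r$sc_pct, r$svp_pct, r$ic_pct, r$ms) >= 0))
    expect_true(all(c(r$sc_pct, r$svp_pct, r$ic_pct, r$ms) <= 100))
  }
})

test_that("unmatched extra peaks never help any score", {
  p <- parse_proteoform("K20me2", h4_toy)
  cfg <- sim_config(seed = 5, completeness = 0.7, ppm_jitter = 2,
                    noise_fraction = 0)
  pk <- simulate_ecd_spectrum(p, cfg)$peaks
  r1 <- score_proteoform(p, pk)
  # append far-off peaks that cannot match anything
  pk2 <- spectrum_peaks(c(pk$value, max(pk$value) + c(1000, 2000, 3000)),
                        c(pk$intensity, rep(500, 3)), "neutral")
  r2 <- score_proteoform(p, pk2)
  expect_equal(r2$sc_pct, r1$sc_pct)
  expect_equal(r2$svp_pct, r1$svp_pct)
  expect_lte(r2$ic_pct, r1$ic_pct)
})

test_that("candidate ranking prefers the planted isomer", {
  truth <- parse_proteoform("N-acS K12ac", h4_toy)
  cfg <- sim_config(seed = 23, completeness = 0.8, ppm_jitter = 2,
                    noise_fraction = 0.2)
  sim <- simulate_ecd_spectrum(truth, cfg)
  cs <- generate_candidates(proteoform(h4_toy), proteoform_mass(truth),
                            ptm_alphabet = c("ac", "me1", "me2", "me3", "ox"))
  tab <- rank_candidates(cs, sim$peaks)
  expect_identical(tab$label[1], "N-acS K12ac")
})
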