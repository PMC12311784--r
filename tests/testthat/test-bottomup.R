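test_that("first-round propionylation labels free amines only", {
  p <- propionylate(proteoform("GSTGGKAPR"), "first")
  expect_identical(format_proteoform(p), "N-propG K6prop")
  expect_equal(proteoform_mass(p), 941.49301, tolerance = 1e-4)
  # acetylated K is blocked: only the N-terminus is labeled
  pk_ac <- propionylate(proteoform("GSTGGKAPR",
                                   data.frame(site = 6, name = "ac")), "first")
  expect_identical(format_proteoform(pk_ac), "N-propG K6ac")
  # me1-K keeps a reactive proton: becomes the composite me1prop
  pk_me1 <- propionylate(proteoform("GSTGGKAPR",
                                    data.frame(site = 6, name = "me1")), "first")
  expect_identical(format_proteoform(pk_me1), "N-propG K6me1prop")
  expect_equal(proteoform_mass(pk_me1) -
                 proteoform_mass(proteoform("GSTGGKAPR")),
               2 * 56.026215 + 14.01565, tolerance = 1e-5)
  # me2/me3 block; a modified N-terminus is not relabeled
  pk_me2 <- propionylate(proteoform("GSTGGKAPR",
                                    data.frame(site = 6, name = "me2")), "first")
  expect_identical(format_proteoform(pk_me2), "N-propG K6me2")
  pn <- propionylate(parse_proteoform("N-acG", "GSTGGKAPR"), "first")
  expect_identical(format_proteoform(pn), "N-acG K6prop")
  # second round touches only the N-terminus
  p2 <- propionylate(proteoform("GSTGGKAPR"), "second")
  expect_identical(format_proteoform(p2), "N-propG")
})

test_that("digestion cleaves after R, never before P, never at K", {
  prot <- propionylate(proteoform(qc_parent), "first")
  peps <- digest(prot, digest_rule(max_missed = 0))
  seqs <- vapply(peps, function(x) x$proteoform$sequence, character(1))
  expect_identical(seqs, c("GVKFR", "GSTGGKAPR", "GKAPATSGMVGPHR"))
  # 0-missed-cleavage products tile the parent exactly
  expect_identical(paste(seqs, collapse = ""), qc_parent)
  # RP motif is protected
  rp <- digest(proteoform("AAARPGGR"), digest_rule(max_missed = 0))
  expect_identical(vapply(rp, function(x) x$proteoform$sequence, character(1)),
                   "AAARPGGR")
  # no R at all: single full-length product
  nr <- digest(proteoform("GGKGGAK"), digest_rule(max_missed = 0))
  expect_equal(length(nr), 1)
  # missed cleavages emit the concatenated forms too
  mc <- digest(prot, digest_rule(max_missed = 1))
  expect_true("GVKFRGSTGGKAPR" %in%
                vapply(mc, function(x) x$proteoform$sequence, character(1)))
})

test_that("peptides inherit parent modifications in local coordinates", {
  prot <- propionylate(parse_proteoform("K11ac", qc_parent), "first")
  peps <- digest(prot, digest_rule(max_missed = 0))
  qc1 <- peps[[which(vapply(peps, function(x) x$proteoform$sequence,
                            character(1)) == "GSTGGKAPR")]]
  expect_equal(qc1$start, 6)
  expect_identical(format_proteoform(qc1$proteoform), "K6ac")
  # protein N-terminal label stays on the first peptide only
  first <- peps[[1]]
  expect_true(0 %in% first$proteoform$mods$site)
})

test_that("the QC target list reproduces the printed products and m/z", {
  tl <- build_target_list(proteoform(qc_parent), "QC", charges = 2)
  z2 <- tl[tl$z == 2 & tl$missed == 0, ]
  expect_true(all(c("GSTGGKAPR", "GKAPATSGMVGPHR") %in% z2$sequence))
  expect_equal(z2$mz[z2$sequence == "GSTGGKAPR"], 471.7538, tolerance = 1e-4)
  expect_equal(z2$mz[z2$sequence == "GKAPATSGMVGPHR"], 739.3826,
               tolerance = 1e-4)
  expect_equal(round(z2$mz[z2$sequence == "GSTGGKAPR"], 2), 471.75)
  expect_equal(round(z2$mz[z2$sequence == "GKAPATSGMVGPHR"], 2), 739.38)
})

test_that("PTM enumeration expands each K to its modification states", {
  # H4-toy 4..17 span: K5/K8/K12/K16 each ac or free (-> prop)
  span <- substr(h4_toy, 4, 17)
  ks <- which(strsplit(span, "")[[1]] == "K")
  site_mods <- stats::setNames(rep(list(c("ac", NA)), length(ks)),
                               as.character(ks))
  forms <- enumerate_ptm_forms(span, site_mods)
  expect_equal(length(forms), 16)
  tl <- build_target_list(forms, "H4toy", charges = 2,
                          rule = digest_rule(max_missed = 0))
  full <- tl[tl$start == 1 & tl$end == nchar(span), ]
  expect_equal(nrow(full), 16)
  # every free amine (peptide N-term + non-ac K) carries exactly one prop
  for (i in seq_len(nrow(full))) {
    p <- parse_proteoform(full$mods[i], full$sequence[i])
    n_prop <- sum(p$mods$name == "prop")
    n_free_k <- length(ks) - sum(p$mods$name == "ac" & p$mods$site > 0)
    expect_equal(n_prop, 1 + n_free_k)
  }
})

test_that("bottom-up masses agree with direct proteoform sums", {
  tl <- build_target_list(proteoform(qc_parent), "QC", charges = c(1, 2, 3))
  for (i in seq_len(nrow(tl))) {
    p <- parse_proteoform(tl$mods[i], tl$sequence[i])
    expect_equal(tl$neutral_mass[i], proteoform_mass(p), tolerance = 1e-6)
    expect_equal(tl$mz[i], mz_from_mass(proteoform_mass(p), tl$z[i]),
                 tolerance = 1e-4)
  }
})

test_that("peptide confirmation filters on precursor then scores b/y", {
  tl <- build_target_list(proteoform(qc_parent), "QC", charges = 2,
                          rule = digest_rule(max_missed = 0))
  qc1 <- tl[tl$sequence == "GSTGGKAPR", ]
  p <- parse_proteoform(qc1$mods, qc1$sequence)
  lad <- fragment_ladder(p, c("b", "y"))
  pk <- spectrum_peaks(mz_from_mass(lad$neutral_mass, 1),
                       rep(100, nrow(lad)), "mz")
  spectra <- list(list(precursor_mz = qc1$mz, charge = 2L, peaks = pk),
                  list(precursor_mz = qc1$mz + 0.05, charge = 2L, peaks = pk))
  out <- confirm_peptides(tl, spectra)
  # spectrum 1 confirms QC1 at full coverage; spectrum 2 fails the
  # 0.01 Da precursor filter and is absent
  expect_true(any(out$sequence == "GSTGGKAPR" & out$spectrum == 1 &
                    out$confirmed))
  expect_equal(out$sc_pct[out$spectrum == 1 & out$sequence == "GSTGGKAPR"], 100)
  expect_false(any(out$spectrum == 2))
})

test_that("positional-isomer peptides are distinguished by reporter b/y ions", {
  span <- substr(h4_toy, 4, 17)  # GKGGKGLGKGGAKR
  k1 <- parse_proteoform("K2ac", span)
  k2 <- parse_proteoform("K5ac", span)
  g <- isomer_group(list(propionylate(k1, "first"), propionylate(k2, "first")))
  rs <- find_reporter_ions(g, series = c("b", "y"))
  expect_true(all(rs$quantifiable))
  # fully deterministic mixture: equal fractions give equal reporter sums
  sim <- simulate_isomer_mixture(g, c(0.5, 0.5),
                                 sim_config(seed = 2, completeness = 1,
                                            ppm_jitter = 0, noise_fraction = 0,
                                            int_sdlog = 0),
                                 series = c("b", "y"))
  q <- quantify_isomers(g, sim$peaks, 1, series = c("b", "y"))
  expect_equal(q$fraction, c(0.5, 0.5))
})
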