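# Seeded simulators for the data shapes the pipeline consumes:
# deconvolved MS1 envelopes with PTM-shifted satellite peaks, ECD/CID
# fragment spectra with partial ladders, ppm jitter and noise peaks, and
# chimeric positional-isomer mixtures. Every generator is deterministic
# under its seed and returns the planted ground truth alongside the data.

#' Simulation configuration
#'
#' @param seed Mandatory integer seed; all randomness flows from it.
#' @param completeness Fraction of theoretical fragments present (0..1).
#' @param ppm_jitter Gaussian s.d. of mass error in ppm.
#' @param noise_fraction Noise peaks as a fraction of signal peaks (0..1):
#'   `round(noise_fraction * n_signal)` uniform-mass noise peaks are
#'   added.
#' @param int_meanlog,int_sdlog Log-normal fragment-intensity parameters.
#'   Noise intensities use the same shape scaled so their median is 10%
#'   of the signal median.
#' @param envelope_jitter_da Gaussian s.d. (Da) on envelope peak masses.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed, completeness = 0.9, ppm_jitter = 2,
                       noise_fraction = 0.1, int_meanlog = log(1000),
                       int_sdlog = 0.5, envelope_jitter_da = 0.002) {
  if (missing(seed)) hf_stop("seed is mandatory", "hf_bad_arg")
  if (completeness < 0 || completeness > 1 ||
      noise_fraction < 0 || noise_fraction > 1)
    hf_stop("fractions must lie in [0, 1]", "hf_bad_arg")
  structure(list(seed = as.integer(seed), completeness = completeness,
                 ppm_jitter = ppm_jitter, noise_fraction = noise_fraction,
                 int_meanlog = int_meanlog, int_sdlog = int_sdlog,
                 envelope_jitter_da = envelope_jitter_da),
            class = "sim_config")
}

# run expr under a seed without touching the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# core sampler shared by the spectrum simulators; returns per-fragment
# rows (kept flag, jittered mass, intensity) without noise
.sample_ladder <- function(ladder, cfg, scale = 1) {
  n <- nrow(ladder)
  kept <- stats::runif(n) < cfg$completeness
  jit <- stats::rnorm(n, 0, cfg$ppm_jitter) * 1e-6
  intensity <- scale * stats::rlnorm(n, cfg$int_meanlog, cfg$int_sdlog)
  data.frame(series = ladder$series, index = ladder$index,
             true_mass = ladder$neutral_mass,
             mass = ladder$neutral_mass * (1 + jit),
             intensity = intensity, kept = kept)
}

.add_noise <- function(masses, intensities, n_signal, precursor_mass, cfg) {
  n_noise <- round(cfg$noise_fraction * n_signal)
  if (n_noise < 1) return(list(mass = numeric(0), intensity = numeric(0)))
  sig_median <- if (length(intensities)) stats::median(intensities) else exp(cfg$int_meanlog)
  nm <- stats::runif(n_noise, 50, max(precursor_mass, 51))
  ni <- stats::rlnorm(n_noise, cfg$int_meanlog, cfg$int_sdlog)
  ni <- ni * (0.1 * sig_median / exp(cfg$int_meanlog))
  list(mass = nm, intensity = ni)
}

#' Simulate an ECD fragment spectrum
#'
#' Samples a `completeness` fraction of the proteoform's c/zdot/a
#' fragments, applies Gaussian ppm jitter, draws log-normal intensities
#' and adds uniform-mass noise peaks over [50 Da, precursor mass].
#'
#' @param p A [proteoform()].
#' @param cfg A [sim_config()].
#' @param series Ion series (default ECD c/zdot/a; use b/y for CID).
#' @return List: `peaks` (a neutral-mode [spectrum_peaks()]) and `truth`
#'   (proteoform, the kept-fragment table, noise count, seed).
#' @export
simulate_ecd_spectrum <- function(p, cfg, series = .ecd_series) {
  stopifnot(inherits(cfg, "sim_config"))
  ladder <- fragment_ladder(p, series)
  precursor <- proteoform_mass(p)
  .with_seed(cfg$seed, {
    samp <- .sample_ladder(ladder, cfg)
    keep <- samp[samp$kept, , drop = FALSE]
    noise <- .add_noise(keep$mass, keep$intensity, nrow(keep), precursor, cfg)
    peaks <- spectrum_peaks(c(keep$mass, noise$mass),
                            c(keep$intensity, noise$intensity),
                            mode = "neutral")
    list(peaks = peaks,
         truth = list(proteoform = p, fragments = keep,
                      n_noise = length(noise$mass), seed = cfg$seed))
  })
}

#' Simulate a deconvolved MS1 envelope
#'
#' One neutral-mass peak per distinct proteoform mass; mass-degenerate
#' proteoforms (positional isomers) collapse into one peak with summed
#' abundance, as they do in a deconvolved spectrum. Small Gaussian Da
#' jitter is applied to the peak positions.
#'
#' @param proteoforms List of [proteoform()] objects.
#' @param abundances Non-negative abundances, same length.
#' @param cfg A [sim_config()].
#' @return List: `envelope` (data.frame `neutral_mass`, `intensity`) and
#'   `truth` (per-peak member lists and true masses).
#' @export
simulate_envelope <- function(proteoforms, abundances, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(proteoforms) != length(abundances) || any(abundances < 0))
    hf_stop("abundances must be non-negative, one per proteoform", "hf_bad_arg")
  masses <- vapply(proteoforms, proteoform_mass, numeric(1))
  key <- round(masses / 0.001)  # isomer collapse at 1 mDa
  groups <- split(seq_along(masses), key)
  true_mass <- vapply(groups, function(i) mean(masses[i]), numeric(1))
  abund <- vapply(groups, function(i) sum(abundances[i]), numeric(1))
  ord <- order(true_mass)
  groups <- groups[ord]; true_mass <- true_mass[ord]; abund <- abund[ord]
  .with_seed(cfg$seed + 1L, {
    obs <- true_mass + stats::rnorm(length(true_mass), 0, cfg$envelope_jitter_da)
    env <- data.frame(neutral_mass = obs, intensity = abund)
    env <- env[order(env$neutral_mass), , drop = FALSE]
    rownames(env) <- NULL
    list(envelope = env,
         truth = list(members = groups, true_mass = true_mass,
                      abundance = abund, seed = cfg$seed))
  })
}

#' Simulate a chimeric positional-isomer fragment spectrum
#'
#' Superposition of the members' spectra: fragments shared between
#' isomers (identical theoretical mass) add their intensity
#' contributions, each scaled by the member's mixture fraction; each
#' distinct theoretical mass is jittered once. Noise is added as in
#' [simulate_ecd_spectrum()].
#'
#' @param group An [isomer_group()].
#' @param fractions Mixture fractions summing to 1 (tolerance 1e-9).
#' @param cfg A [sim_config()].
#' @param series Ion series.
#' @return List: `peaks` and `truth` (fractions, per-isomer kept
#'   fragments).
#' @export
simulate_isomer_mixture <- function(group, fractions, cfg,
                                    series = .ecd_series) {
  stopifnot(inherits(group, "isomer_group"), inherits(cfg, "sim_config"))
  k <- length(group$proteoforms)
  if (length(fractions) != k) hf_stop("one fraction per isomer", "hf_bad_arg")
  if (abs(sum(fractions) - 1) > 1e-9)
    hf_stop("fractions must sum to 1", "hf_bad_fractions")
  ladders <- lapply(group$proteoforms, fragment_ladder, series = series)
  .with_seed(cfg$seed, {
    contrib <- list()
    kept_tabs <- vector("list", k)
    for (i in seq_len(k)) {
      samp <- .sample_ladder(ladders[[i]], cfg, scale = fractions[i])
      keep <- samp[samp$kept & fractions[i] > 0, , drop = FALSE]
      kept_tabs[[i]] <- keep
      if (nrow(keep))
        contrib[[length(contrib) + 1L]] <-
          data.frame(key = round(keep$true_mass / 1e-6),
                     true_mass = keep$true_mass, intensity = keep$intensity)
    }
    if (length(contrib)) {
      all_c <- do.call(rbind, contrib)
      agg_i <- tapply(all_c$intensity, all_c$key, sum)
      agg_m <- tapply(all_c$true_mass, all_c$key, mean)
      ord <- order(agg_m)
      true_mass <- as.numeric(agg_m)[ord]
      intensity <- as.numeric(agg_i)[ord]
    } else {
      true_mass <- numeric(0); intensity <- numeric(0)
    }
    jit <- stats::rnorm(length(true_mass), 0, cfg$ppm_jitter) * 1e-6
    mass <- true_mass * (1 + jit)
    noise <- .add_noise(mass, intensity, length(mass), group$mass, cfg)
    peaks <- spectrum_peaks(c(mass, noise$mass),
                            c(intensity, noise$intensity), mode = "neutral")
    list(peaks = peaks,
         truth = list(fractions = fractions, fragments = kept_tabs,
                      n_noise = length(noise$mass), seed = cfg$seed))
  })
}
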