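# Positional-isomer quantitation from isomer-specific reporter ions.
# Co-isolated isomers share one MS1 envelope peak; the MS1 area is
# apportioned by the relative reporter intensity of each isomer:
# relative abundance = (isomer reporter intensity / combined reporter
# intensity) x MS1 area. Because members of a group can have very
# different numbers of distinguishing fragments (in groups of 3+ a
# member flanked by near sites may have few), each member's summed
# reporter intensity is normalized by its theoretical reporter count
# before the ratio is taken; otherwise the apportionment is biased
# toward reporter-rich members regardless of abundance.

#' Group mass-degenerate proteoforms
#'
#' Validates that all members are isomeric within `tol_da` on neutral
#' mass (default 0.01 Da) and wraps them with labels.
#'
#' @param proteoforms List of >= 2 [proteoform()] objects.
#' @param tol_da Grouping tolerance in Da.
#' @return Object of class `isomer_group`.
#' @export
isomer_group <- function(proteoforms, tol_da = 0.01) {
  if (length(proteoforms) < 2)
    hf_stop("an isomer group needs at least 2 members", "hf_bad_arg")
  masses <- vapply(proteoforms, proteoform_mass, numeric(1))
  if (diff(range(masses)) > tol_da)
    hf_stop("members are not isomeric within tolerance", "hf_not_isomeric")
  labels <- vapply(proteoforms, format_proteoform, character(1))
  structure(list(proteoforms = proteoforms, labels = labels,
                 mass = mean(masses)),
            class = "isomer_group")
}

#' Find isomer-specific reporter ions
#'
#' For each group member, the theoretical fragments whose neutral mass
#' differs by more than `tol_ppm` from every fragment of every other
#' member. Only such fragments can attribute intensity unambiguously. A
#' member with no reporters is flagged unquantifiable.
#'
#' @param group An [isomer_group()].
#' @param series Ion series (default ECD c/zdot/a).
#' @param tol_ppm Separation tolerance in ppm (default 10).
#' @return Object of class `reporter_set`: list with `reporters` (one
#'   fragment data.frame per member) and `quantifiable` (logical).
#' @export
find_reporter_ions <- function(group, series = .ecd_series, tol_ppm = 10) {
  stopifnot(inherits(group, "isomer_group"))
  ladders <- lapply(group$proteoforms, fragment_ladder, series = series)
  k <- length(ladders)
  reporters <- vector("list", k)
  for (i in seq_len(k)) {
    own <- ladders[[i]]
    others <- sort(unlist(lapply(ladders[-i], `[[`, "neutral_mass")))
    if (!length(others)) { reporters[[i]] <- own; next }
    is_rep <- vapply(own$neutral_mass, function(m) {
      j <- findInterval(m, others)
      near <- c(if (j >= 1) others[j], if (j < length(others)) others[j + 1])
      all(abs(m - near) / m * 1e6 > tol_ppm)
    }, logical(1))
    reporters[[i]] <- own[is_rep, , drop = FALSE]
  }
  structure(list(reporters = reporters,
                 labels = group$labels,
                 quantifiable = vapply(reporters, nrow, integer(1)) > 0),
            class = "reporter_set")
}

#' Quantify co-isolated positional isomers
#'
#' Matches each member's reporter ions in the (chimeric) fragment
#' spectrum, sums their intensities, normalizes each sum by the member's
#' theoretical reporter count (so members with unequal numbers of
#' distinguishing fragments are comparable), and apportions the MS1
#' envelope area: fraction_i = (S_i / n_i) / sum_j (S_j / n_j), relative
#' abundance_i = fraction_i x `ms1_area`. If no reporter of any member is
#' observed the group is returned unquantified (no division by zero).
#'
#' @param group An [isomer_group()].
#' @param peaks A [spectrum_peaks()] in neutral mode (the matched MS/MS
#'   spectrum of the co-isolated precursors).
#' @param ms1_area MS1 envelope area shared by the group (>= 0).
#' @param series,tol_ppm Passed to [find_reporter_ions()] / peak matching.
#' @param reporters Optional precomputed [find_reporter_ions()] result for
#'   this group (avoids recomputing the ladders when quantifying many
#'   spectra of one group).
#' @return data.frame: `label`, `n_reporters`, `reporter_intensity`,
#'   `fraction`, `relative_abundance`; attribute `quantified` (logical).
#' @export
quantify_isomers <- function(group, peaks, ms1_area, series = .ecd_series,
                             tol_ppm = 10, reporters = NULL) {
  if (ms1_area < 0) hf_stop("ms1_area must be >= 0", "hf_bad_arg")
  rs <- if (is.null(reporters)) find_reporter_ions(group, series, tol_ppm)
        else reporters
  obs <- peaks$value
  csum <- c(0, cumsum(peaks$intensity))
  ints <- numeric(length(rs$reporters))
  nrep <- integer(length(rs$reporters))
  for (i in seq_along(rs$reporters)) {
    rep_m <- rs$reporters[[i]]$neutral_mass
    nrep[i] <- length(rep_m)
    if (!length(rep_m) || !length(obs)) next
    tol <- tol_ppm * rep_m * 1e-6
    lo <- findInterval(rep_m - tol, obs)       # peaks strictly below window
    hi <- findInterval(rep_m + tol, obs)       # peaks up to window top
    ints[i] <- sum(csum[hi + 1L] - csum[lo + 1L])
  }
  norm <- ifelse(nrep > 0, ints / nrep, 0)
  total <- sum(norm)
  quantified <- total > 0
  frac <- if (quantified) norm / total else rep(NA_real_, length(ints))
  out <- data.frame(
    label = rs$labels,
    n_reporters = nrep,
    reporter_intensity = ints,
    fraction = frac,
    relative_abundance = if (quantified) frac * ms1_area else rep(NA_real_, length(ints)),
    stringsAsFactors = FALSE
  )
  attr(out, "quantified") <- quantified
  out
}
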