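# Fragment-ladder matching against observed peaks and the four proteoform
# confirmation scores: sequence coverage (%SC), sequence validation
# percentage (%SVP), intensity coverage (%IC) and MS score = %SC x %IC.

.series_rank <- c(c = 1, zdot = 2, z = 3, b = 4, y = 5, a = 6)
.ecd_series <- c("c", "zdot", "a")
.cid_series <- c("b", "y")

#' Construct a centroided peak list
#'
#' @param value Peak positions: neutral masses (Da) or m/z, per `mode`.
#' @param intensity Non-negative intensities.
#' @param mode `"neutral"` or `"mz"`.
#' @param precursor_charge Optional precursor charge (m/z mode).
#' @return Object of class `spectrum_peaks`: data.frame `value`,
#'   `intensity` sorted by value, with attributes `mode` and
#'   `precursor_charge`.
#' @export
spectrum_peaks <- function(value, intensity, mode = c("neutral", "mz"),
                           precursor_charge = NULL) {
  mode <- match.arg(mode)
  if (length(value) != length(intensity))
    hf_stop("value and intensity lengths differ", "hf_bad_arg")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    hf_stop("intensities must be finite and non-negative", "hf_bad_arg")
  ord <- order(value)
  value <- value[ord]; intensity <- intensity[ord]
  if (anyDuplicated(value)) {
    # merge exact duplicates so values are strictly increasing
    intensity <- as.numeric(tapply(intensity, value, sum))
    value <- sort(unique(value))
  }
  structure(data.frame(value = value, intensity = intensity),
            mode = mode, precursor_charge = precursor_charge,
            class = c("spectrum_peaks", "data.frame"))
}

#' Match theoretical fragments to observed peaks
#'
#' Each observed peak is assigned to at most one theoretical fragment: the
#' one with the smallest absolute ppm error within `tol_ppm`. In m/z mode
#' fragment charges 1..`max_charge` are enumerated. Ties are broken
#' deterministically: lower charge, then series order c, zdot, z, b, y, a,
#' then lower index.
#'
#' @param p A [proteoform()].
#' @param peaks A [spectrum_peaks()] object.
#' @param series Ion series to consider (default ECD: c, zdot, a).
#' @param tol_ppm Match tolerance in ppm (> 0; default 10).
#' @param max_charge Maximum fragment charge in m/z mode (default 1).
#' @return data.frame with one row per matched peak: `series`, `index`,
#'   `charge`, `theoretical`, `peak` (row index into `peaks`), `observed`,
#'   `error_ppm`.
#' @export
match_fragments <- function(p, peaks, series = .ecd_series, tol_ppm = 10,
                            max_charge = 1) {
  if (tol_ppm <= 0) hf_stop("tol_ppm must be > 0", "hf_bad_arg")
  empty <- data.frame(series = character(0), index = integer(0),
                      charge = integer(0), theoretical = numeric(0),
                      peak = integer(0), observed = numeric(0),
                      error_ppm = numeric(0))
  if (!nrow(peaks)) return(empty)
  mode <- attr(peaks, "mode")
  ladder <- fragment_ladder(p, series)
  if (!nrow(ladder)) return(empty)
  if (identical(mode, "mz")) {
    if (max_charge < 1) hf_stop("max_charge must be >= 1 in m/z mode", "hf_bad_arg")
    theo <- do.call(rbind, lapply(seq_len(max_charge), function(z) {
      data.frame(series = ladder$series, index = ladder$index, charge = z,
                 theoretical = mz_from_mass(ladder$neutral_mass, z))
    }))
  } else {
    theo <- data.frame(series = ladder$series, index = ladder$index,
                       charge = NA_integer_, theoretical = ladder$neutral_mass)
  }
  theo <- theo[order(theo$theoretical), , drop = FALSE]
  tv <- theo$theoretical
  out <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    obs <- peaks$value[i]
    tol <- tol_ppm * obs * 1e-6
    lo <- findInterval(obs - tol, tv) + 1L
    hi <- findInterval(obs + tol, tv)
    if (hi < lo) next
    cand <- theo[lo:hi, , drop = FALSE]
    ppm <- (obs - cand$theoretical) / cand$theoretical * 1e6
    keep <- abs(ppm) <= tol_ppm
    if (!any(keep)) next
    cand <- cand[keep, , drop = FALSE]; ppm <- ppm[keep]
    ord <- order(abs(ppm), cand$charge, .series_rank[cand$series], cand$index)
    j <- ord[1]
    out[[i]] <- data.frame(series = cand$series[j], index = cand$index[j],
                           charge = cand$charge[j],
                           theoretical = cand$theoretical[j],
                           peak = i, observed = obs, error_ppm = ppm[j])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# cleavage sites evidenced by a match set: N-terminal series index i
# evidences cleavage i; C-terminal series index j evidences cleavage n-j
.cleavage_set <- function(matches, n) {
  cl <- c(0L, n)
  if (nrow(matches)) {
    nt <- matches$series %in% .series_nterm
    cl <- c(cl, matches$index[nt], n - matches$index[!nt])
  }
  sort(unique(cl))
}

.confirmed_residues <- function(matches, n) {
  cl <- .cleavage_set(matches, n)
  inC <- logical(n + 1)
  inC[cl + 1L] <- TRUE
  which(inC[seq_len(n)] & inC[seq_len(n) + 1L])
}

#' Sequence coverage (%SC)
#'
#' A residue is confirmed when both of its flanking backbone cleavage
#' sites are evidenced by a matched fragment (the two termini count as
#' evidenced). %SC is 100 x confirmed / n.
#'
#' @param matches Output of [match_fragments()].
#' @param n Sequence length (>= 1).
#' @return Percentage in 0..100.
#' @export
sequence_coverage <- function(matches, n) {
  if (n < 1) hf_stop("n must be >= 1", "hf_bad_arg")
  100 * length(.confirmed_residues(matches, n)) / n
}

#' Sequence validation percentage (%SVP)
#'
#' The fraction of residues confirmed in unbroken runs from the two
#' terminals: length of the maximal confirmed prefix plus the maximal
#' confirmed suffix on the remaining residues, over n. Always <= %SC.
#'
#' @inheritParams sequence_coverage
#' @return Percentage in 0..100.
#' @export
sequence_validation <- function(matches, n) {
  if (n < 1) hf_stop("n must be >= 1", "hf_bad_arg")
  conf <- logical(n)
  conf[.confirmed_residues(matches, n)] <- TRUE
  pre <- if (all(conf)) n else which(!conf)[1] - 1L
  rest <- conf[seq_len(n) > pre]
  suf <- if (!length(rest)) 0L
         else if (all(rest)) length(rest)
         else length(rest) - max(which(!rest))
  100 * (pre + suf) / n
}

#' Intensity coverage (%IC)
#'
#' Fraction of total peak intensity carried by peaks holding at least one
#' fragment match, each peak counted once.
#'
#' @param matches Output of [match_fragments()].
#' @param peaks The [spectrum_peaks()] that were matched.
#' @return Percentage in 0..100.
#' @export
intensity_coverage <- function(matches, peaks) {
  total <- sum(peaks$intensity)
  if (total <= 0) hf_stop("total peak intensity is zero", "hf_zero_intensity")
  # clamp: summation order can overshoot 100 by a few ulp when all match
  min(100, 100 * sum(peaks$intensity[unique(matches$peak)]) / total)
}

#' MS score
#'
#' The product score MS = %SC x %IC / 100, on a 0..100 scale.
#'
#' @param sc_pct,ic_pct Percentages in 0..100.
#' @return Score in 0..100.
#' @export
ms_score <- function(sc_pct, ic_pct) {
  if (any(sc_pct < 0 | sc_pct > 100 | ic_pct < 0 | ic_pct > 100))
    hf_stop("scores must lie in [0, 100]", "hf_bad_arg")
  sc_pct * ic_pct / 100
}

#' Score a proteoform candidate against a spectrum
#'
#' Runs [match_fragments()] and composes the four confirmation metrics.
#'
#' @inheritParams match_fragments
#' @return Object of class `match_result`: list with `proteoform`,
#'   `matches`, `sc_pct`, `svp_pct`, `ic_pct`, `ms`.
#' @export
score_proteoform <- function(p, peaks, series = .ecd_series, tol_ppm = 10,
                             max_charge = 1) {
  n <- proteoform_length(p)
  m <- match_fragments(p, peaks, series, tol_ppm, max_charge)
  if (!nrow(peaks)) {
    sc <- 0; svp <- 0; ic <- 0
  } else {
    sc <- sequence_coverage(m, n)
    svp <- sequence_validation(m, n)
    ic <- intensity_coverage(m, peaks)
  }
  structure(list(proteoform = p, matches = m, sc_pct = sc, svp_pct = svp,
                 ic_pct = ic, ms = ms_score(sc, ic)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: %s\n", format_proteoform(x$proteoform)))
  cat(sprintf("  %d matched fragments | SC %.2f%% | SVP %.2f%% | IC %.2f%% | MS %.2f\n",
              nrow(x$matches), x$sc_pct, x$svp_pct, x$ic_pct, x$ms))
  invisible(x)
}

#' Rank candidate proteoforms against one spectrum
#'
#' Scores every candidate and orders them by MS score (descending), then
#' %SC, then fewer modifications.
#'
#' @param candidates A `candidate_set` from [generate_candidates()] or a
#'   list of proteoforms.
#' @inheritParams match_fragments
#' @return data.frame, best candidate first: `label`, `n_mods`, `sc_pct`,
#'   `svp_pct`, `ic_pct`, `ms`, plus attribute `results` holding the full
#'   `match_result` list in ranked order.
#' @export
rank_candidates <- function(candidates, peaks, series = .ecd_series,
                            tol_ppm = 10, max_charge = 1) {
  plist <- if (inherits(candidates, "candidate_set")) candidates$candidates
           else candidates
  if (!length(plist)) hf_stop("no candidates to rank", "hf_bad_arg")
  results <- lapply(plist, score_proteoform, peaks = peaks, series = series,
                    tol_ppm = tol_ppm, max_charge = max_charge)
  tab <- data.frame(
    label = vapply(plist, format_proteoform, character(1)),
    n_mods = vapply(plist, function(p) nrow(p$mods), integer(1)),
    sc_pct = vapply(results, `[[`, numeric(1), "sc_pct"),
    svp_pct = vapply(results, `[[`, numeric(1), "svp_pct"),
    ic_pct = vapply(results, `[[`, numeric(1), "ic_pct"),
    ms = vapply(results, `[[`, numeric(1), "ms"),
    stringsAsFactors = FALSE
  )
  ord <- order(-tab$ms, -tab$sc_pct, tab$n_mods, tab$label)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "results") <- results[ord]
  tab
}
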