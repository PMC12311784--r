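# MS1-level annotation: explain deconvolved neutral-mass shifts as PTM
# combinations or single amino acid variants (SAAVs), and expand a base
# sequence into localized proteoform candidates for MS/MS scoring.

.core_ptms <- c("me1", "me2", "me3", "ac", "ox")

# all multisets of size 1..k from x (names), as a list of character vectors
.ptm_multisets <- function(x, k) {
  out <- list()
  grow <- function(prefix, start, depth) {
    for (i in seq(start, length(x))) {
      comb <- c(prefix, x[i])
      out[[length(out) + 1L]] <<- comb
      if (depth < k) grow(comb, i, depth + 1L)
    }
  }
  if (k >= 1 && length(x)) grow(character(0), 1L, 1L)
  out
}

#' Build a mass-shift explanation table
#'
#' Enumerates every multiset of up to `max_ptms` modifications from the
#' alphabet, plus all 380 ordered single-residue substitutions X->Y with
#' delta = mass(Y) - mass(X). Numerically degenerate entries (e.g. `ox` at
#' +15.99491 vs `A->S` at +15.99492) are retained on purpose: resolving
#' them is the job of fragment evidence, not of this table.
#'
#' @param max_ptms Maximum number of PTMs in a combination (>= 1).
#' @param ptm_alphabet Character vector of modification names present in
#'   [modification_table()]. Defaults to me1/me2/me3/ac/ox.
#' @return data.frame with columns `kind` (`ptm` or `substitution`),
#'   `description` (e.g. `"ac+me1"`, `"K->R"`) and `delta` (Da).
#' @examples
#' tab <- build_delta_table(2)
#' tab[tab$description == "K->R", ]
#' @export
build_delta_table <- function(max_ptms = 2, ptm_alphabet = .core_ptms) {
  if (max_ptms < 1) hf_stop("max_ptms must be >= 1", "hf_bad_arg")
  deltas <- .mod_delta(ptm_alphabet)
  combos <- .ptm_multisets(ptm_alphabet, max_ptms)
  ptm <- data.frame(
    kind = "ptm",
    description = vapply(combos, function(cc) paste(sort(cc), collapse = "+"),
                         character(1)),
    delta = vapply(combos, function(cc) sum(deltas[match(cc, ptm_alphabet)]),
                   numeric(1)),
    stringsAsFactors = FALSE
  )
  ptm <- ptm[!duplicated(ptm$description), , drop = FALSE]
  aa <- names(.residue_mass_table)
  grid <- expand.grid(from = aa, to = aa, stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, , drop = FALSE]
  sub <- data.frame(
    kind = "substitution",
    description = paste0(grid$from, "->", grid$to),
    delta = .residue_mass_table[grid$to] - .residue_mass_table[grid$from],
    stringsAsFactors = FALSE
  )
  out <- rbind(ptm, sub)
  rownames(out) <- NULL
  out
}

#' Explain an observed mass shift
#'
#' Ranks the table entries within `tol_da` of the observation by absolute
#' mass error; ties go to PTM combinations before substitutions, then
#' lexicographic description. An empty result means the shift is
#' unexplained at this tolerance (the H2A +26.27 Da case) and is a valid
#' return, not an error.
#'
#' @param delta_obs Observed neutral-mass shift (Da).
#' @param table A table from [build_delta_table()].
#' @param tol_da Absolute tolerance (Da), > 0.
#' @return data.frame with `kind`, `description`, `delta`, `error_da`,
#'   `error_ppm` (relative to the observed shift; NA at zero shift),
#'   sorted best-first.
#' @examples
#' explain_mass_shift(28.01, build_delta_table(2), tol_da = 0.05)
#' @export
explain_mass_shift <- function(delta_obs, table, tol_da = 0.02) {
  if (tol_da <= 0) hf_stop("tol_da must be > 0", "hf_bad_arg")
  # mass-silent entries (I<->L, delta exactly 0) cannot explain any shift
  table <- table[table$delta != 0, , drop = FALSE]
  err <- table$delta - delta_obs
  keep <- abs(err) <= tol_da
  out <- table[keep, , drop = FALSE]
  out$error_da <- err[keep]
  out$error_ppm <- if (delta_obs != 0) out$error_da / abs(delta_obs) * 1e6
                   else rep(NA_real_, nrow(out))
  # round the error key so elementally identical deltas (me1 vs D->E, both
  # +CH2; me2 vs me1+me1) tie exactly and fall through to the deterministic
  # breaks: PTM before substitution, fewer components, lexicographic
  n_comp <- ifelse(out$kind == "ptm",
                   lengths(regmatches(out$description,
                                      gregexpr("\\+", out$description))) + 1L,
                   1L)
  ord <- order(round(abs(out$error_da), 9),
               match(out$kind, c("ptm", "substitution")), n_comp,
               out$description)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# default localization rules: where each PTM may sit on a given sequence
.allowed_positions <- function(mod, res) {
  sites <- .mod_sites[[mod]]
  pos <- which(res %in% setdiff(sites, "N-term"))
  if ("N-term" %in% sites) pos <- c(0L, pos)
  sort(pos)
}

#' Generate localized proteoform candidates for an observed mass
#'
#' Finds every PTM multiset (up to `max_mods` modifications from the
#' alphabet) whose total delta matches `observed_mass` minus the base
#' proteoform mass within `tol_ppm`, and enumerates all site placements
#' allowed by the modification site rules (one modification per site, at
#' most one on the N-terminus). Generation order is deterministic
#' (lexicographic in modification names, then sites); the candidate list
#' is capped with an explicit truncation flag, never silently.
#'
#' @param base Base [proteoform()] (its existing mods are kept fixed).
#' @param observed_mass Observed deconvolved neutral mass (Da).
#' @param ptm_alphabet Modification names to consider.
#' @param max_mods Maximum number of added modifications (default 6).
#' @param tol_ppm Match tolerance in ppm of the observed mass (default 10).
#' @param cap Hard cap on the number of candidates (default 10000).
#' @return Object of class `candidate_set`: list with `base`,
#'   `observed_mass`, `candidates` (list of proteoforms), `error_da`
#'   (per candidate) and `truncated`.
#' @examples
#' cs <- generate_candidates(proteoform("SGRGKGGKGLGKGGAKR"),
#'                           proteoform_mass(proteoform("SGRGKGGKGLGKGGAKR")) + 42.010565)
#' vapply(cs$candidates, format_proteoform, character(1))
#' @export
generate_candidates <- function(base, observed_mass, ptm_alphabet = .core_ptms,
                                max_mods = 6, tol_ppm = 10, cap = 10000) {
  stopifnot(inherits(base, "proteoform"))
  base_mass <- proteoform_mass(base)
  tol_da <- tol_ppm * observed_mass * 1e-6
  target <- observed_mass - base_mass
  if (target < -tol_da)
    hf_stop("mass deficit: observed mass below base proteoform mass", "hf_mass_deficit")
  res <- strsplit(base$sequence, "")[[1]]
  occupied <- base$mods$site
  deltas <- .mod_delta(ptm_alphabet)

  # multisets (size 0..max_mods) whose summed delta hits the target
  sets <- list()
  if (abs(target) <= tol_da) sets[[1]] <- character(0)
  alpha <- sort(ptm_alphabet)
  adelta <- .mod_delta(alpha)
  grow <- function(prefix, start, total) {
    for (i in seq(start, length(alpha))) {
      tot <- total + adelta[i]
      if (tot > target + tol_da + 1e-9) next  # all deltas positive except none; ox>0 too
      comb <- c(prefix, alpha[i])
      if (abs(tot - target) <= tol_da) sets[[length(sets) + 1L]] <<- comb
      if (length(comb) < max_mods) grow(comb, i, tot)
    }
  }
  if (max_mods >= 1) grow(character(0), 1L, 0)

  candidates <- list()
  truncated <- FALSE
  # place one multiset: injective site assignment, identical mods in
  # increasing site order, <=1 N-terminal mod overall
  place <- function(mods, idx, used, placement) {
    if (truncated) return()
    if (idx > length(mods)) {
      sites <- vapply(placement, `[[`, numeric(1), 1)
      names_ <- vapply(placement, function(x) x[[2]], character(1))
      p <- proteoform(base$sequence,
                      data.frame(site = c(base$mods$site, as.integer(sites)),
                                 name = c(base$mods$name, names_)))
      if (length(candidates) >= cap) { truncated <<- TRUE; return() }
      candidates[[length(candidates) + 1L]] <<- p
      return()
    }
    mod <- mods[idx]
    pos <- .allowed_positions(mod, res)
    # identical mods placed in strictly increasing site order to kill
    # permutation duplicates
    if (idx > 1 && mods[idx - 1] == mod) {
      prev_site <- placement[[idx - 1]][[1]]
      pos <- pos[pos > prev_site]
    }
    pos <- setdiff(pos, c(used, occupied))
    for (s in pos) {
      place(mods, idx + 1L, c(used, s), c(placement, list(list(s, mod))))
      if (truncated) return()
    }
  }
  for (ms in sets) {
    if (!length(ms)) {
      if (length(candidates) < cap) candidates[[length(candidates) + 1L]] <- base
      next
    }
    place(sort(ms), 1L, numeric(0), list())
    if (truncated) break
  }
  err <- vapply(candidates, function(p) proteoform_mass(p) - observed_mass,
                numeric(1))
  structure(list(base = base, observed_mass = observed_mass,
                 candidates = candidates, error_da = err,
                 truncated = truncated),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d candidate(s) for observed mass %.5f Da%s\n",
              length(x$candidates), x$observed_mass,
              if (x$truncated) " [TRUNCATED]" else ""))
  for (i in seq_along(x$candidates)) {
    cat(sprintf("  %s (err %+.5f Da)\n",
                format_proteoform(x$candidates[[i]]), x$error_da[i]))
  }
  invisible(x)
}

#' Label a deconvolved MS1 envelope
#'
#' Explains each peak's shift relative to the base proteoform mass (or,
#' with `relative_to = "previous"`, relative to the nearest lighter
#' explained peak) using a delta table. Peaks with no explanation within
#' tolerance are labeled `unexplained` and keep their residual.
#'
#' @param env data.frame with columns `neutral_mass`, `intensity`
#'   (strictly increasing masses).
#' @param base Base [proteoform()].
#' @param table Delta table from [build_delta_table()].
#' @param tol_da Labeling tolerance in Da (default 0.02, matching
#'   two-decimal envelope reporting).
#' @param relative_to `"base"` (default) or `"previous"`.
#' @return The envelope with added columns `label`, `delta_obs`,
#'   `error_da`.
#' @export
annotate_envelope <- function(env, base, table = build_delta_table(2),
                              tol_da = 0.02, relative_to = c("base", "previous")) {
  relative_to <- match.arg(relative_to)
  if (!nrow(env)) hf_stop("empty envelope", "hf_bad_arg")
  if (is.unsorted(env$neutral_mass, strictly = TRUE))
    hf_stop("envelope masses must be strictly increasing", "hf_bad_arg")
  base_mass <- proteoform_mass(base)
  ref <- base_mass
  label <- character(nrow(env)); dobs <- numeric(nrow(env)); errd <- rep(NA_real_, nrow(env))
  for (i in seq_len(nrow(env))) {
    d <- env$neutral_mass[i] - ref
    dobs[i] <- d
    if (abs(d) <= tol_da) {
      label[i] <- if (relative_to == "base") "unmodified" else "isobaric"
      errd[i] <- d
    } else {
      ex <- explain_mass_shift(d, table, tol_da)
      if (nrow(ex)) {
        label[i] <- ex$description[1]
        errd[i] <- ex$error_da[1]
      } else {
        label[i] <- "unexplained"
      }
    }
    if (relative_to == "previous" && label[i] != "unexplained")
      ref <- env$neutral_mass[i]
  }
  env$label <- label
  env$delta_obs <- dobs
  env$error_da <- errd
  env
}
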