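# Bottom-up histone workflow: in silico propionylation, Arg-C-like
# tryptic digestion (K blocked by the propionyl/acetyl/methyl groups),
# target-list construction and peptide-level confirmation against CID
# spectra.

#' In silico propionylation
#'
#' First round (intact protein): adds a propionyl group (+56.02621 Da) to
#' the N-terminus unless it already carries a modification (N-terminal
#' acetyl or methyl states block the label), and to every lysine that is
#' unmodified or monomethylated (me1 retains a reactive proton, so the K
#' becomes `me1prop`; ac/me2/me3 block). Second round (after digestion):
#' labels only free peptide N-termini.
#'
#' @param p A [proteoform()].
#' @param round `"first"` or `"second"`.
#' @return The propionylated [proteoform()].
#' @export
propionylate <- function(p, round = c("first", "second")) {
  round <- match.arg(round)
  stopifnot(inherits(p, "proteoform"))
  res <- strsplit(p$sequence, "")[[1]]
  mods <- p$mods
  modded <- function(site) site %in% mods$site
  add <- function(site, name) {
    mods <<- rbind(mods, data.frame(site = as.integer(site), name = name))
  }
  if (!modded(0L)) add(0L, "prop")
  if (round == "first") {
    for (k in which(res == "K")) {
      if (!modded(k)) add(k, "prop")
      else if (mods$name[mods$site == k] == "me1")
        mods$name[mods$site == k] <- "me1prop"
    }
  }
  proteoform(p$sequence, mods)
}

#' Digestion rule
#'
#' Trypsin on a propionylated histone behaves like Arg-C: cleavage
#' C-terminal of R, never before P, and never at K (the epsilon amine is
#' blocked by propionyl/acetyl/methyl groups).
#'
#' @param cleave_after Residues cut C-terminally (default `"R"`).
#' @param no_cleave_before Residues blocking cleavage on the C-side
#'   (default `"P"`).
#' @param max_missed Maximum missed cleavages (default 1).
#' @return A `digest_rule` list.
#' @export
digest_rule <- function(cleave_after = "R", no_cleave_before = "P",
                        max_missed = 1) {
  if (max_missed < 0) hf_stop("max_missed must be >= 0", "hf_bad_arg")
  structure(list(cleave_after = cleave_after,
                 no_cleave_before = no_cleave_before,
                 max_missed = as.integer(max_missed)),
            class = "digest_rule")
}

#' In silico digestion of a proteoform
#'
#' Cleaves per the rule and emits every product with 0..`max_missed`
#' missed cleavages. Each peptide carries its parent span and the parent
#' modifications re-indexed to peptide coordinates (a protein N-terminal
#' modification stays only on the first peptide).
#'
#' @param p A [proteoform()] (typically after first-round
#'   [propionylate()]).
#' @param rule A [digest_rule()].
#' @return List of peptide records: `start`, `end`, `missed`,
#'   `proteoform`.
#' @export
digest <- function(p, rule = digest_rule()) {
  stopifnot(inherits(p, "proteoform"), inherits(rule, "digest_rule"))
  res <- strsplit(p$sequence, "")[[1]]
  n <- length(res)
  cut <- which(res %in% strsplit(rule$cleave_after, "")[[1]])
  cut <- cut[cut < n]
  if (nzchar(rule$no_cleave_before))
    cut <- cut[!res[cut + 1L] %in% strsplit(rule$no_cleave_before, "")[[1]]]
  bounds <- c(0L, cut, n)  # peptide i = bounds[i]+1 .. bounds[i+1]
  k <- length(bounds) - 1L
  out <- list()
  for (i in seq_len(k)) {
    for (mc in 0:min(rule$max_missed, k - i)) {
      start <- bounds[i] + 1L
      end <- bounds[i + 1L + mc]
      seq_i <- substr(p$sequence, start, end)
      keep <- p$mods$site >= start & p$mods$site <= end |
              (p$mods$site == 0L & start == 1L)
      mods_i <- p$mods[keep, , drop = FALSE]
      if (nrow(mods_i))
        mods_i$site <- ifelse(mods_i$site == 0L, 0L, mods_i$site - start + 1L)
      out[[length(out) + 1L]] <- list(
        start = start, end = end, missed = mc,
        proteoform = proteoform(seq_i, mods_i))
    }
  }
  out
}

#' Enumerate PTM forms of a sequence over variable sites
#'
#' Helper for target-list construction: each named site may carry one of
#' the listed modifications or none (`NA`), and all combinations are
#' produced. Unmodified lysines then pick up propionyl downstream.
#'
#' @param sequence Protein/peptide sequence.
#' @param site_mods Named list: names are sites (integer as character; "0"
#'   for N-term), values are character vectors of modification names,
#'   with `NA` allowed meaning "unmodified".
#' @return List of [proteoform()] objects (deterministic order).
#' @export
enumerate_ptm_forms <- function(sequence, site_mods) {
  sites <- as.integer(names(site_mods))
  choices <- lapply(site_mods, function(x) x)
  grid <- expand.grid(choices, stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    picked <- !is.na(unlist(grid[r, ], use.names = FALSE))
    out[[r]] <- proteoform(sequence, data.frame(
      site = sites[picked],
      name = unlist(grid[r, picked], use.names = FALSE)))
  }
  out
}

#' Build a bottom-up peptide target list
#'
#' Runs the full derivatization pipeline on each protein form: first-round
#' propionylation, digestion, second-round propionylation of the new
#' peptide N-termini, then expected m/z per charge.
#'
#' @param forms List of [proteoform()] objects (PTM forms of one protein),
#'   or a single proteoform.
#' @param protein_id Identifier carried into the table.
#' @param charges Integer vector of charges (default 2).
#' @param rule A [digest_rule()].
#' @return data.frame: `protein`, `start`, `end`, `sequence`, `mods`,
#'   `missed`, `z`, `mz`, `neutral_mass`.
#' @examples
#' tl <- build_target_list(proteoform("GVKFRGSTGGKAPRGKAPATSGMVGPHR"), "QC")
#' tl[tl$sequence == "GSTGGKAPR" & tl$z == 2, ]
#' @export
build_target_list <- function(forms, protein_id = "protein", charges = 2,
                              rule = digest_rule()) {
  if (inherits(forms, "proteoform")) forms <- list(forms)
  rows <- list()
  seen <- character(0)
  for (f in forms) {
    prot <- propionylate(f, "first")
    for (pep in digest(prot, rule)) {
      pp <- propionylate(pep$proteoform, "second")
      key <- paste(pep$start, pep$end, format_proteoform(pp))
      if (key %in% seen) next
      seen <- c(seen, key)
      m <- proteoform_mass(pp)
      for (z in charges) {
        rows[[length(rows) + 1L]] <- data.frame(
          protein = protein_id, start = pep$start, end = pep$end,
          sequence = pp$sequence, mods = format_proteoform(pp),
          missed = pep$missed, z = as.integer(z),
          mz = mz_from_mass(m, z), neutral_mass = m,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Confirm peptide targets against CID spectra
#'
#' Each spectrum is first filtered on precursor m/z within `prec_tol_da`
#' (the monoisotopic stand-in for the precursor/isotope check), then the
#' surviving target is scored with b/y fragment matching.
#'
#' @param targets Target table from [build_target_list()].
#' @param spectra List of spectra: each a list with `precursor_mz`,
#'   `charge` and `peaks` (a [spectrum_peaks()]).
#' @param prec_tol_da Precursor tolerance in Da on m/z (default 0.01).
#' @param tol_ppm Fragment tolerance in ppm (default 10).
#' @return data.frame: one row per target x matching spectrum with
#'   `sc_pct`, `svp_pct`, `ic_pct`, `ms`, `confirmed` (any fragment
#'   matched); targets without a precursor match are absent.
#' @export
confirm_peptides <- function(targets, spectra, prec_tol_da = 0.01,
                             tol_ppm = 10) {
  rows <- list()
  for (si in seq_along(spectra)) {
    sp <- spectra[[si]]
    hit <- which(abs(targets$mz - sp$precursor_mz) <= prec_tol_da &
                 targets$z == sp$charge)
    for (ti in hit) {
      p <- parse_proteoform(targets$mods[ti], targets$sequence[ti])
      r <- score_proteoform(p, sp$peaks, series = .cid_series,
                            tol_ppm = tol_ppm, max_charge = sp$charge)
      rows[[length(rows) + 1L]] <- data.frame(
        protein = targets$protein[ti], start = targets$start[ti],
        end = targets$end[ti], sequence = targets$sequence[ti],
        mods = targets$mods[ti], z = targets$z[ti],
        spectrum = si, sc_pct = r$sc_pct, svp_pct = r$svp_pct,
        ic_pct = r$ic_pct, ms = r$ms,
        confirmed = nrow(r$matches) > 0,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(protein = character(0), start = integer(0),
                      end = integer(0), sequence = character(0),
                      mods = character(0), z = integer(0),
                      spectrum = integer(0), sc_pct = numeric(0),
                      svp_pct = numeric(0), ic_pct = numeric(0),
                      ms = numeric(0), confirmed = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
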