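# Monoisotopic mass chemistry: residues, modifications, proteoforms and
# fragment-ion ladders. All masses are monoisotopic Da computed from
# elemental composition, so the residue table is consistent with the
# elemental masses by construction.

# Monoisotopic element masses (Da).
.element_mass <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

# Elemental composition of the 20 standard amino acid residues
# (the in-chain residue, i.e. amino acid minus water).
.residue_formula <- list(
  A = c(C = 3, H = 5, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  G = c(C = 2, H = 3, N = 1, O = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  K = c(C = 6, H = 12, N = 2, O = 1),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  P = c(C = 5, H = 7, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  T = c(C = 4, H = 7, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  V = c(C = 5, H = 9, N = 1, O = 1)
)

#' Monoisotopic mass of an elemental formula
#'
#' @param counts Named integer vector of element counts; names must be
#'   among C, H, N, O, S.
#' @return Monoisotopic mass in Da.
#' @keywords internal
formula_mass <- function(counts) {
  bad <- setdiff(names(counts), names(.element_mass))
  if (length(bad)) hf_stop(paste0("unknown element: ", bad[1]), "hf_unknown_element")
  sum(.element_mass[names(counts)] * counts)
}

.residue_mass_table <- vapply(.residue_formula, formula_mass, numeric(1))

#' Monoisotopic residue masses
#'
#' Residue (in-chain) masses of the 20 standard amino acids, computed from
#' elemental composition. I and L are isomeric; K and Q differ by
#' 0.03639 Da, the smallest gap in the table.
#'
#' @return Named numeric vector, one-letter code to monoisotopic Da.
#' @examples
#' residue_masses()[["G"]]
#' @export
residue_masses <- function() .residue_mass_table

#' Embedded mass constants
#'
#' Proton, water, ammonia, carbon monoxide and hydrogen-atom monoisotopic
#' masses used for m/z conversion and fragment-series offsets.
#'
#' @return Named numeric vector (Da).
#' @export
mass_constants <- function() {
  c(
    proton  = 1.0072765,
    water   = formula_mass(c(H = 2, O = 1)),     # 18.010565
    ammonia = formula_mass(c(N = 1, H = 3)),     # 17.026549
    co      = formula_mass(c(C = 1, O = 1)),     # 27.994915
    hydrogen = .element_mass[["H"]]              # 1.007825
  )
}

.mass_const <- c(
  proton = 1.0072765,
  water = 2 * 1.00782503207 + 15.9949146196,
  ammonia = 14.0030740048 + 3 * 1.00782503207,
  co = 12 + 15.9949146196,
  hydrogen = 1.00782503207
)

# Modification elemental compositions. `me1prop` is the composite state of
# a monomethylated lysine that still carries a free proton on the epsilon
# amine and therefore also receives a propionyl group during derivatization.
.mod_formula <- list(
  me1 = c(C = 1, H = 2),
  me2 = c(C = 2, H = 4),
  me3 = c(C = 3, H = 6),
  ac  = c(C = 2, H = 2, O = 1),
  ox  = c(O = 1),
  prop = c(C = 3, H = 4, O = 1),
  me1prop = c(C = 4, H = 6, O = 1)
)

.mod_sites <- list(
  me1 = c("K", "R", "N-term"),
  me2 = c("K", "R", "N-term"),
  me3 = c("K", "R", "N-term"),
  ac  = c("K", "N-term"),
  ox  = c("M"),
  prop = c("K", "N-term"),
  me1prop = c("K")
)

#' Modification table
#'
#' The modifications handled by default: mono/di/trimethylation
#' (+14.01565, +28.03130, +42.04695 Da), acetylation (+42.01056 Da),
#' oxidation (+15.99491 Da), propionylation (+56.02621 Da, the bottom-up
#' derivatization label) and the composite `me1prop` state. Site rules:
#' methylation on K/R or the protein N-terminus, acetylation on K or the
#' N-terminus, oxidation on M, propionylation on K or a peptide N-terminus.
#'
#' @return data.frame with columns `name`, `delta` (monoisotopic Da) and
#'   `sites` (comma-separated allowed residue letters / `N-term`).
#' @examples
#' modification_table()
#' @export
modification_table <- function() {
  data.frame(
    name = names(.mod_formula),
    delta = vapply(.mod_formula, formula_mass, numeric(1)),
    sites = vapply(.mod_sites, paste, character(1), collapse = ","),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

.mod_delta_table <- vapply(.mod_formula, formula_mass, numeric(1))

#' @keywords internal
hf_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hf_error")))
}

.mod_delta <- function(name) {
  d <- .mod_delta_table[name]
  if (anyNA(d)) {
    hf_stop(paste0("unknown modification: ",
                   name[which(is.na(d))[1]]), "hf_unknown_mod")
  }
  unname(d)
}

.check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) < 1)
    hf_stop("sequence must be a single non-empty string", "hf_bad_sequence")
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(res, names(.residue_mass_table))
  if (length(bad)) hf_stop(paste0("unknown residue: ", bad[1]), "hf_unknown_residue")
  res
}

#' Construct a proteoform
#'
#' A proteoform is a primary sequence plus a set of localized
#' modifications. Sites are 1-based residue indices on the processed
#' (initiator-Met-free) sequence; site 0 denotes the N-terminus. At most
#' one modification per site, and each modification must be allowed at its
#' site (see [modification_table()]).
#'
#' @param sequence One-letter amino acid string.
#' @param mods Optional data.frame with columns `site` (integer) and
#'   `name` (modification name), or a list of `list(site, name)` pairs.
#' @return Object of class `proteoform`.
#' @examples
#' proteoform("SGRGK", mods = data.frame(site = c(0, 5), name = c("ac", "me2")))
#' @export
proteoform <- function(sequence, mods = NULL) {
  res <- .check_sequence(sequence)
  n <- length(res)
  if (is.null(mods)) {
    mods <- data.frame(site = integer(0), name = character(0),
                       stringsAsFactors = FALSE)
  } else if (is.list(mods) && !is.data.frame(mods)) {
    mods <- data.frame(
      site = vapply(mods, function(m) as.integer(m[[1]]), integer(1)),
      name = vapply(mods, function(m) as.character(m[[2]]), character(1)),
      stringsAsFactors = FALSE
    )
  }
  mods$site <- as.integer(mods$site)
  mods$name <- as.character(mods$name)
  if (nrow(mods)) {
    .mod_delta(mods$name)  # errors on unknown names
    if (any(mods$site < 0 | mods$site > n))
      hf_stop("modification site outside sequence", "hf_bad_site")
    if (anyDuplicated(mods$site))
      hf_stop("two modifications share one site", "hf_duplicate_site")
    for (i in seq_len(nrow(mods))) {
      allowed <- .mod_sites[[mods$name[i]]]
      ok <- if (mods$site[i] == 0L) "N-term" %in% allowed
            else res[mods$site[i]] %in% allowed
      if (!ok) {
        hf_stop(sprintf("modification %s not allowed at site %d (%s)",
                        mods$name[i], mods$site[i],
                        if (mods$site[i] == 0L) "N-term" else res[mods$site[i]]),
                "hf_disallowed_site")
      }
    }
    mods <- mods[order(mods$site), , drop = FALSE]
    rownames(mods) <- NULL
  }
  structure(list(sequence = sequence, mods = mods), class = "proteoform")
}

#' @export
print.proteoform <- function(x, ...) {
  cat("proteoform:", x$sequence, "\n")
  cat("  mods:", format_proteoform(x), "\n")
  cat("  neutral mass:", sprintf("%.5f Da", proteoform_mass(x)), "\n")
  invisible(x)
}

#' Neutral monoisotopic mass of a proteoform
#'
#' Sum of residue masses, one water, and all modification deltas.
#'
#' @param p A [proteoform()].
#' @return Monoisotopic neutral mass (Da).
#' @examples
#' proteoform_mass(proteoform("AG"))  # 146.06913
#' @export
proteoform_mass <- function(p) {
  stopifnot(inherits(p, "proteoform"))
  res <- strsplit(p$sequence, "")[[1]]
  m <- sum(.residue_mass_table[res]) + .mass_const[["water"]]
  if (nrow(p$mods)) m <- m + sum(.mod_delta(p$mods$name))
  m
}

#' Convert a neutral mass to m/z
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param z Positive integer charge.
#' @return (mass + z * 1.0072765) / z.
#' @examples
#' mz_from_mass(941.49301, 2)  # 471.7538, the QC1 precursor
#' @export
mz_from_mass <- function(mass, z) {
  if (any(z < 1) || any(z != round(z)))
    hf_stop("charge must be a positive integer", "hf_bad_charge")
  (mass + z * .mass_const[["proton"]]) / z
}

.series_nterm <- c("a", "b", "c")
.series_cterm <- c("y", "z", "zdot")
.all_series <- c(.series_nterm, .series_cterm)

#' Theoretical fragment-ion ladder
#'
#' Neutral masses of terminal fragments for the requested ion series.
#' N-terminal series: `b_i` is the sum of residues 1..i plus any N-terminal
#' and in-span modification deltas; `a_i = b_i - CO`; `c_i = b_i + NH3`.
#' C-terminal series: `y_j` is the sum of the last j residues plus water
#' and in-span deltas; `z_j = y_j - NH3`; `zdot_j = z_j + H` (the radical
#' z+1 species that electron-capture dissociation predominantly yields).
#'
#' @param p A [proteoform()].
#' @param series Character vector drawn from `a,b,c,y,z,zdot`.
#' @return data.frame with columns `series`, `index` (1..n-1) and
#'   `neutral_mass` (Da).
#' @examples
#' fragment_ladder(proteoform("AG"), "c")  # c1 = 88.06366
#' @export
fragment_ladder <- function(p, series = c("c", "zdot")) {
  stopifnot(inherits(p, "proteoform"))
  bad <- setdiff(series, .all_series)
  if (length(bad)) hf_stop(paste0("unknown ion series: ", bad[1]), "hf_bad_series")
  res <- strsplit(p$sequence, "")[[1]]
  n <- length(res)
  if (n < 2) {
    return(data.frame(series = character(0), index = integer(0),
                      neutral_mass = numeric(0)))
  }
  delta_at <- numeric(n)  # per-residue mod deltas
  nterm_delta <- 0
  if (nrow(p$mods)) {
    for (i in seq_len(nrow(p$mods))) {
      d <- .mod_delta(p$mods$name[i])
      if (p$mods$site[i] == 0L) nterm_delta <- nterm_delta + d
      else delta_at[p$mods$site[i]] <- delta_at[p$mods$site[i]] + d
    }
  }
  prefix <- cumsum(.residue_mass_table[res] + delta_at)
  b <- prefix[seq_len(n - 1)] + nterm_delta
  suffix <- rev(cumsum(rev(.residue_mass_table[res] + delta_at)))
  y <- suffix[seq(2, n)] + .mass_const[["water"]]  # y_j spans residues (n-j+1)..n
  y <- rev(y)  # index j = 1..n-1
  out <- lapply(series, function(s) {
    mass <- switch(s,
      b = b,
      a = b - .mass_const[["co"]],
      c = b + .mass_const[["ammonia"]],
      y = y,
      z = y - .mass_const[["ammonia"]],
      zdot = y - .mass_const[["ammonia"]] + .mass_const[["hydrogen"]]
    )
    data.frame(series = s, index = seq_len(n - 1), neutral_mass = unname(mass))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Number of residues in a proteoform sequence
#' @param p A [proteoform()].
#' @return Integer length.
#' @export
proteoform_length <- function(p) nchar(p$sequence)

#' Format a proteoform label
#'
#' Writes the compact field notation: an `N-<mod><first-letter>` token for
#' an N-terminal modification followed by `<residue><pos><mod>` tokens,
#' e.g. `N-acS K12ac K20me2`; `unmodified` when there are no
#' modifications. Round-trips through [parse_proteoform()].
#'
#' @param p A [proteoform()].
#' @return Single character label.
#' @export
format_proteoform <- function(p) {
  stopifnot(inherits(p, "proteoform"))
  if (!nrow(p$mods)) return("unmodified")
  res <- strsplit(p$sequence, "")[[1]]
  toks <- character(0)
  m <- p$mods[order(p$mods$site), , drop = FALSE]
  for (i in seq_len(nrow(m))) {
    toks <- c(toks, if (m$site[i] == 0L) {
      paste0("N-", m$name[i], res[1])
    } else {
      paste0(res[m$site[i]], m$site[i], m$name[i])
    })
  }
  paste(toks, collapse = " ")
}

#' Parse a proteoform label
#'
#' Inverse of [format_proteoform()]: reads tokens like `N-acS`, `K12ac`,
#' `M56ox` against a given sequence.
#'
#' @param label Label string (`unmodified` or space-separated tokens).
#' @param sequence The primary sequence the sites refer to.
#' @return A [proteoform()].
#' @examples
#' parse_proteoform("N-acS K20me2", "SGRGKGGKGLGKGGAKRHRKVLRD")
#' @export
parse_proteoform <- function(label, sequence) {
  res <- .check_sequence(sequence)
  label <- trimws(label)
  if (label == "" || identical(tolower(label), "unmodified"))
    return(proteoform(sequence))
  toks <- strsplit(label, "[[:space:]]+")[[1]]
  sites <- integer(0); names_ <- character(0)
  for (tok in toks) {
    if (grepl("^N-", tok)) {
      m <- regmatches(tok, regexec("^N-([a-z0-9]+?)([A-Z])$", tok))[[1]]
      if (length(m) != 3)
        hf_stop(paste0("cannot parse N-terminal token: ", tok), "hf_bad_label")
      if (m[3] != res[1])
        hf_stop(sprintf("N-terminal token %s disagrees with sequence start %s",
                        tok, res[1]), "hf_bad_label")
      sites <- c(sites, 0L); names_ <- c(names_, m[2])
    } else {
      m <- regmatches(tok, regexec("^([A-Z])([0-9]+)([a-z0-9]+)$", tok))[[1]]
      if (length(m) != 4)
        hf_stop(paste0("cannot parse token: ", tok), "hf_bad_label")
      pos <- as.integer(m[3])
      if (pos < 1 || pos > length(res) || res[pos] != m[2])
        hf_stop(sprintf("token %s does not match sequence (position %d is %s)",
                        tok, pos,
                        if (pos >= 1 && pos <= length(res)) res[pos] else "absent"),
                "hf_bad_label")
      sites <- c(sites, pos); names_ <- c(names_, m[4])
    }
  }
  proteoform(sequence, data.frame(site = sites, name = names_))
}
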