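# Readers and writers for the plain-text interchange formats: FASTA
# (delegated to Biostrings), MGF peak lists, two-column TSV neutral-mass
# lists and envelopes, CSV reports and JSON run configs.

#' Read a protein FASTA file
#'
#' @param path FASTA file (multi-record, wrapped lines).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) hf_stop(paste0("no such file: ", path), "hf_io")
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))  # id = first token
  out
}

#' Write a protein FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' Read an MGF peak-list file
#'
#' Dialect: `BEGIN IONS`/`END IONS` blocks, `TITLE=`, `PEPMASS=` (m/z and
#' optional intensity), `CHARGE=` with trailing sign (e.g. `2+`), and
#' two-column whitespace-separated peak lines. Unknown headers are
#' ignored with a warning.
#'
#' @param path MGF file.
#' @return List of spectra: each a list with `title`, `precursor_mz`,
#'   `charge` and `peaks` (an m/z-mode [spectrum_peaks()]).
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) hf_stop(paste0("no such file: ", path), "hf_io")
  lines <- readLines(path)
  spectra <- list()
  i <- 1L; n <- length(lines)
  while (i <= n) {
    if (trimws(lines[i]) != "BEGIN IONS") { i <- i + 1L; next }
    title <- NA_character_; pepmass <- NA_real_; charge <- NA_integer_
    mz <- numeric(0); int <- numeric(0)
    i <- i + 1L
    repeat {
      if (i > n) hf_stop(sprintf("%s: unterminated BEGIN IONS block", path), "hf_io")
      ln <- trimws(lines[i])
      if (ln == "END IONS") { i <- i + 1L; break }
      if (grepl("^TITLE=", ln)) {
        title <- sub("^TITLE=", "", ln)
      } else if (grepl("^PEPMASS=", ln)) {
        pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "[[:space:]]+")[[1]][1])
      } else if (grepl("^CHARGE=", ln)) {
        cs <- sub("^CHARGE=", "", ln)
        sign <- if (grepl("-$", cs)) -1L else 1L
        charge <- sign * as.integer(gsub("[^0-9]", "", cs))
      } else if (grepl("^[A-Z_]+=", ln)) {
        warning(sprintf("%s line %d: ignoring header %s", path, i,
                        sub("=.*$", "", ln)))
      } else if (nzchar(ln)) {
        parts <- strsplit(ln, "[[:space:]]+")[[1]]
        vals <- suppressWarnings(as.numeric(parts[1:2]))
        if (anyNA(vals))
          hf_stop(sprintf("%s line %d: malformed peak line '%s'", path, i, ln),
                  "hf_io")
        mz <- c(mz, vals[1]); int <- c(int, vals[2])
      }
      i <- i + 1L
    }
    spectra[[length(spectra) + 1L]] <- list(
      title = title, precursor_mz = pepmass, charge = charge,
      peaks = spectrum_peaks(mz, int, mode = "mz", precursor_charge = charge))
  }
  spectra
}

#' Write spectra to MGF
#'
#' @param spectra List as returned by [read_mgf()] (peaks in m/z mode).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    if (!is.na(sp$title)) writeLines(paste0("TITLE=", sp$title), con)
    if (!is.na(sp$precursor_mz))
      writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mz), con)
    if (!is.na(sp$charge))
      writeLines(sprintf("CHARGE=%d%s", abs(sp$charge),
                         if (sp$charge < 0) "-" else "+"), con)
    writeLines(sprintf("%.6f %.4f", sp$peaks$value, sp$peaks$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

.read_two_col_tsv <- function(path, col1, col2) {
  if (!file.exists(path)) hf_stop(paste0("no such file: ", path), "hf_io")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c(col1, col2) %in% names(df)))
    hf_stop(sprintf("%s: expected header '%s\t%s'", path, col1, col2), "hf_io")
  if (any(!is.finite(df[[col1]])) || any(!is.finite(df[[col2]])))
    hf_stop(sprintf("%s: non-numeric values", path), "hf_io")
  df[c(col1, col2)]
}

#' Read a deconvolved neutral-mass envelope TSV
#'
#' Two tab-separated columns `neutral_mass` and `intensity` with a header
#' line.
#'
#' @param path TSV file.
#' @return data.frame `neutral_mass`, `intensity`, sorted by mass.
#' @export
read_envelope_tsv <- function(path) {
  df <- .read_two_col_tsv(path, "neutral_mass", "intensity")
  df[order(df$neutral_mass), , drop = FALSE]
}

#' Write an envelope TSV
#' @param env data.frame `neutral_mass`, `intensity`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_envelope_tsv <- function(env, path) {
  utils::write.table(env[c("neutral_mass", "intensity")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a neutral fragment-mass TSV as a peak list
#'
#' Columns `mass` and `intensity`, header required.
#'
#' @param path TSV file.
#' @return A neutral-mode [spectrum_peaks()].
#' @export
read_peaks_tsv <- function(path) {
  df <- .read_two_col_tsv(path, "mass", "intensity")
  spectrum_peaks(df$mass, df$intensity, mode = "neutral")
}

#' Write a neutral peak list TSV
#' @param peaks A [spectrum_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_tsv <- function(peaks, path) {
  utils::write.table(data.frame(mass = peaks$value, intensity = peaks$intensity),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.default_config <- function() {
  list(denovo_tol_ppm = 15, fragment_tol_ppm = 10, precursor_tol_da = 0.01,
       ms1_tol_da = 0.02, series_ecd = .ecd_series, series_cid = .cid_series,
       max_mods = 6, candidate_cap = 10000, min_hsp_score = 6, seed = 1L)
}

#' Read a JSON run configuration
#'
#' Unspecified fields fall back to the documented defaults (fragment
#' 10 ppm, de novo 15 ppm, precursor 0.01 Da, ECD series c/zdot/a, CID
#' series b/y).
#'
#' @param path JSON file, or `NULL` for pure defaults.
#' @return Named list of settings, with a `config_hash` provenance field.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- .default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) hf_stop(paste0("no such file: ", path), "hf_io")
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad)) warning("ignoring unknown config field(s): ",
                             paste(bad, collapse = ", "))
    cfg[intersect(names(user), names(cfg))] <-
      user[intersect(names(user), names(cfg))]
  }
  if (any(unlist(cfg[c("denovo_tol_ppm", "fragment_tol_ppm",
                       "precursor_tol_da", "ms1_tol_da")]) <= 0))
    hf_stop("tolerances must be positive", "hf_bad_config")
  bad_series <- setdiff(c(cfg$series_ecd, cfg$series_cid), .all_series)
  if (length(bad_series))
    hf_stop(paste0("unknown ion series in config: ", bad_series[1]),
            "hf_bad_config")
  cfg$config_hash <- config_hash(cfg)
  cfg
}

#' Provenance hash of a configuration
#'
#' A small polynomial rolling hash of the canonical JSON serialization,
#' carried in every report so outputs can be traced to their settings.
#'
#' @param cfg A configuration list.
#' @return 8-hex-digit string.
#' @export
config_hash <- function(cfg) {
  cfg$config_hash <- NULL
  s <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE, digits = NA)
  h <- 17
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 4294967296
  sprintf("%08x", h)
}
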