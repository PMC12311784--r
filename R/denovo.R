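# De novo sequence tags from fragment-mass ladders, and protein
# identification by an ungapped high-scoring-pair (HSP) search of the
# tags against a FASTA database.
#
# Tag extraction is a spectrum-graph walk: peaks are nodes, and a directed
# edge joins two peaks whose mass gap matches a residue mass within
# tolerance. Every maximal path spells a candidate amino acid string. I/L
# are isobaric and emitted as "L"; K vs Q (0.036 Da apart) is decided by
# closest mass and flagged ambiguous when the tolerance cannot separate
# them.

#' Extract de novo sequence tags from a fragment ladder
#'
#' @param masses Sorted neutral fragment masses (Da) from one ion series
#'   direction (e.g. deconvolved c ions).
#' @param tol_da Gap tolerance in Da (default 0.01; at the paper-style
#'   15 ppm on sub-2-kDa fragments this is the right order).
#' @param min_length Minimum tag length in residues (default 2).
#' @param max_tags Cap on emitted tags (deterministic truncation).
#' @return data.frame of tags: `tag` (residue string, I/L as L),
#'   `prefix_mass` (mass of the peak preceding the first gap),
#'   `suffix_mass` (mass of the last peak), `length`, `ambiguous`
#'   (TRUE when any K/Q call was within 2x tol of both). Ordered by
#'   prefix mass then decreasing length.
#' @examples
#' extract_tags(c(74.04801, 145.08512, 232.11715))  # tag "AS"
#' @export
extract_tags <- function(masses, tol_da = 0.01, min_length = 2, max_tags = 10000) {
  masses <- sort(unique(masses))
  n <- length(masses)
  empty <- data.frame(tag = character(0), prefix_mass = numeric(0),
                      suffix_mass = numeric(0), length = integer(0),
                      ambiguous = logical(0))
  if (n < min_length + 1) return(empty)
  rt <- .residue_mass_table
  rt_sorted <- sort(rt)
  max_gap <- max(rt) + tol_da
  # adjacency: edges[[u]] = data.frame(to, letter, ambiguous)
  edges <- vector("list", n)
  has_in <- logical(n)
  for (u in seq_len(n - 1)) {
    vs <- which(masses > masses[u] + min(rt) - tol_da &
                masses <= masses[u] + max_gap)
    vs <- vs[vs > u]
    if (!length(vs)) next
    rows <- list()
    for (v in vs) {
      gap <- masses[v] - masses[u]
      errs <- abs(rt - gap)
      if (min(errs) > tol_da) next
      hit <- names(rt)[which.min(errs)]
      # canonical emission: I/L -> L; K/Q by closest mass
      amb <- FALSE
      if (hit %in% c("K", "Q")) {
        other <- setdiff(c("K", "Q"), hit)
        amb <- abs(errs[[hit]] - errs[[other]]) < 2 * tol_da && errs[[other] ] <= tol_da
      }
      letter <- if (hit == "I") "L" else hit
      rows[[length(rows) + 1L]] <- data.frame(to = v, letter = letter,
                                              ambiguous = amb)
      has_in[v] <- TRUE
    }
    if (length(rows)) edges[[u]] <- do.call(rbind, rows)
  }
  has_out <- !vapply(edges, is.null, logical(1))
  starts <- which(has_out & !has_in)
  tags <- list()
  truncated <- FALSE
  walk <- function(u, letters, amb) {
    if (truncated) return()
    e <- edges[[u]]
    if (is.null(e)) {
      if (length(letters) >= min_length) {
        if (length(tags) >= max_tags) { truncated <<- TRUE; return() }
        tags[[length(tags) + 1L]] <<- list(
          tag = paste(letters, collapse = ""),
          prefix_mass = NA_real_, suffix_mass = masses[u],
          ambiguous = any(amb))
      }
      return()
    }
    for (k in seq_len(nrow(e)))
      walk(e$to[k], c(letters, e$letter[k]), c(amb, e$ambiguous[k]))
  }
  out <- list()
  for (s in starts) {
    tags <- list(); truncated <- FALSE
    walk(s, character(0), logical(0))
    for (t in tags) {
      t$prefix_mass <- masses[s]
      out[[length(out) + 1L]] <- t
    }
  }
  if (!length(out)) return(empty)
  df <- data.frame(
    tag = vapply(out, `[[`, character(1), "tag"),
    prefix_mass = vapply(out, `[[`, numeric(1), "prefix_mass"),
    suffix_mass = vapply(out, `[[`, numeric(1), "suffix_mass"),
    ambiguous = vapply(out, `[[`, logical(1), "ambiguous"),
    stringsAsFactors = FALSE
  )
  df$length <- nchar(df$tag)
  df <- df[!duplicated(df[c("tag", "prefix_mass")]), , drop = FALSE]
  df <- df[order(df$prefix_mass, -df$length, df$tag), , drop = FALSE]
  if (nrow(df) > max_tags) df <- df[seq_len(max_tags), , drop = FALSE]
  rownames(df) <- NULL
  df[c("tag", "prefix_mass", "suffix_mass", "length", "ambiguous")]
}

# canonicalize for scoring: I==L, K==Q
.canon <- function(s) chartr("IQ", "LK", toupper(s))

# best ungapped local alignment of tag vs subject under {match +2
# (I==L, K==Q), mismatch -1}; returns score and subject/query coords
.best_hsp <- function(tagc, subc, match = 2, mismatch = -1) {
  m <- length(tagc); n <- length(subc)
  best <- list(score = -Inf, qstart = 0L, qend = 0L, sstart = 0L, send = 0L)
  # diagonals: subject offset o means tag position j aligns to subject o+j
  for (o in seq(1 - m, n - 1)) {
    j0 <- max(1L, 1L - o); j1 <- min(m, n - o)
    if (j1 < j0) next
    cur <- 0; cur_start <- j0
    for (j in seq(j0, j1)) {
      x <- if (tagc[j] == subc[o + j]) match else mismatch
      if (cur <= 0) { cur <- x; cur_start <- j } else cur <- cur + x
      if (cur > best$score) {
        best <- list(score = cur, qstart = cur_start, qend = j,
                     sstart = o + cur_start, send = o + j)
      }
    }
  }
  best
}

# vectorized best-score over all diagonals (no coordinates); used to skip
# the scalar scan for hopeless tag x protein pairs
.best_hsp_score <- function(tagc_int, subc_int, match = 2, mismatch = -1) {
  m <- length(tagc_int); n <- length(subc_int)
  offs <- seq(1 - m, n - 1)
  cur <- rep(0, length(offs)); best <- rep(-Inf, length(offs))
  for (j in seq_len(m)) {
    sp <- offs + j
    x <- rep(-Inf, length(offs))
    ok <- sp >= 1 & sp <= n
    x[ok] <- ifelse(subc_int[sp[ok]] == tagc_int[j], match, mismatch)
    cur <- pmax(cur, 0) + x
    best <- pmax(best, cur)
  }
  max(best)
}

#' HSP homology search of sequence tags against a protein database
#'
#' For every tag x protein pair the best ungapped local alignment is
#' computed under the fixed scoring scheme: match +2 (I/L and K/Q count
#' as matches), mismatch -1, no gaps. HSPs scoring at least
#' `min_hsp_score` are retained; each protein's total score is the sum of
#' its best non-overlapping (on subject coordinates) HSPs across all
#' tags. Scores are comparable within this scheme only, not to published
#' MS-BLAST totals.
#'
#' @param tags Character vector of tag strings, or the data.frame from
#'   [extract_tags()].
#' @param database Named character vector of protein sequences (e.g. from
#'   [read_fasta()]).
#' @param min_hsp_score Minimum retained HSP score (default 6, i.e. three
#'   clean matches).
#' @param match,mismatch Scoring parameters.
#' @return data.frame of hits ranked by `total_score` (ties by protein
#'   id): `protein`, `total_score`, `n_hsp`, `rank`; attribute `hsps`
#'   holds the per-HSP table (`protein`, `tag`, `score`, `qstart`,
#'   `qend`, `sstart`, `send`, `kept`).
#' @export
hsp_search <- function(tags, database, min_hsp_score = 6, match = 2,
                       mismatch = -1) {
  if (is.data.frame(tags)) tags <- tags$tag
  if (!length(database)) hf_stop("empty database", "hf_bad_arg")
  if (is.null(names(database)) || any(!nzchar(names(database))))
    hf_stop("database sequences must be named", "hf_bad_arg")
  tags <- tags[nzchar(tags)]
  sub_int <- lapply(database, function(s) utf8ToInt(.canon(s)))
  hsp_rows <- list()
  for (t in tags) {
    tagc <- strsplit(.canon(t), "")[[1]]
    tag_int <- utf8ToInt(.canon(t))
    for (pid in names(database)) {
      if (.best_hsp_score(tag_int, sub_int[[pid]], match, mismatch) < min_hsp_score)
        next
      sc <- strsplit(.canon(database[[pid]]), "")[[1]]
      h <- .best_hsp(tagc, sc, match, mismatch)
      hsp_rows[[length(hsp_rows) + 1L]] <- data.frame(
        protein = pid, tag = t, score = h$score,
        qstart = h$qstart, qend = h$qend,
        sstart = h$sstart, send = h$send,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hsp_rows)) {
    out <- data.frame(protein = character(0), total_score = numeric(0),
                      n_hsp = integer(0), rank = integer(0))
    attr(out, "hsps") <- data.frame()
    return(out)
  }
  hsps <- do.call(rbind, hsp_rows)
  # per protein: greedy selection of non-overlapping HSPs by score
  hsps$kept <- FALSE
  totals <- list()
  for (pid in unique(hsps$protein)) {
    idx <- which(hsps$protein == pid)
    idx <- idx[order(-hsps$score[idx], hsps$sstart[idx], hsps$tag[idx])]
    taken <- matrix(numeric(0), ncol = 2)
    for (i in idx) {
      s <- hsps$sstart[i]; e <- hsps$send[i]
      if (nrow(taken) && any(s <= taken[, 2] & e >= taken[, 1])) next
      taken <- rbind(taken, c(s, e))
      hsps$kept[i] <- TRUE
    }
    kept <- hsps$kept & hsps$protein == pid
    totals[[pid]] <- data.frame(protein = pid,
                                total_score = sum(hsps$score[kept]),
                                n_hsp = sum(kept))
  }
  out <- do.call(rbind, totals)
  out <- out[order(-out$total_score, out$protein), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "hsps") <- hsps
  out
}
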