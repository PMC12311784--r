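# Shared fixtures and independent oracles. Oracles are deliberately naive
# (brute force / per-definition) and never call the code path they check.

# 50-residue H4 N-terminal-like toy sequence (K5/K8/K12/K16/K20 layout)
h4_toy <- "SGRGKGGKGLGKGGAKRHRKVLRDNIQGITKPAIRRLARRGGVKRISGLI"

qc_parent <- "GVKFRGSTGGKAPRGKAPATSGMVGPHR"

# independently maintained reference residue masses (5 dp, literature)
ref_residue_masses <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)

# per-definition %SC from an explicit cleavage set (Eq 1 reading)
oracle_sc_from_cleavages <- function(cleavages, n) {
  C <- union(c(0, n), cleavages)
  confirmed <- sum(vapply(seq_len(n), function(k)
    (k - 1) %in% C && k %in% C, logical(1)))
  100 * confirmed / n
}

# build a minimal match table evidencing given cleavage sites via c ions
matches_from_cleavages <- function(cleavages, n) {
  cl <- setdiff(cleavages, c(0, n))
  data.frame(series = rep("c", length(cl)), index = as.integer(cl),
             charge = rep(NA_integer_, length(cl)),
             theoretical = rep(NA_real_, length(cl)),
             peak = seq_along(cl), observed = rep(NA_real_, length(cl)),
             error_ppm = rep(0, length(cl)))
}

# naive exhaustive candidate enumeration: all assignments of up to
# max_mods (site, mod) pairs, filtered by mass, site rules and
# disjointness; returns sorted labels
oracle_candidates <- function(sequence, observed_mass, alphabet,
                              max_mods = 3, tol_ppm = 10) {
  res <- strsplit(sequence, "")[[1]]
  modtab <- modification_table()
  pairs <- list()
  for (mod in alphabet) {
    sites <- strsplit(modtab$sites[modtab$name == mod], ",")[[1]]
    pos <- which(res %in% setdiff(sites, "N-term"))
    if ("N-term" %in% sites) pos <- c(0L, pos)
    for (s in pos) pairs[[length(pairs) + 1L]] <- list(site = s, mod = mod)
  }
  base_mass <- proteoform_mass(proteoform(sequence))
  tol_da <- tol_ppm * observed_mass * 1e-6
  deltas <- modtab$delta[match(alphabet, modtab$name)]
  names(deltas) <- alphabet
  labels <- character(0)
  if (abs(base_mass - observed_mass) <= tol_da) labels <- "unmodified"
  for (k in seq_len(max_mods)) {
    if (length(pairs) < k) break
    for (comb in utils::combn(seq_along(pairs), k, simplify = FALSE)) {
      sel <- pairs[comb]
      sites <- vapply(sel, `[[`, numeric(1), "site")
      if (anyDuplicated(sites)) next
      mods <- vapply(sel, `[[`, character(1), "mod")
      total <- base_mass + sum(deltas[mods])
      if (abs(total - observed_mass) > tol_da) next
      p <- proteoform(sequence, data.frame(site = sites, name = mods))
      labels <- c(labels, format_proteoform(p))
    }
  }
  sort(unique(labels))
}

# brute-force best ungapped local alignment score (all segment pairs)
oracle_best_hsp <- function(query, subject, match = 2, mismatch = -1) {
  canon <- function(s) chartr("IQ", "LK", s)
  q <- strsplit(canon(query), "")[[1]]
  s <- strsplit(canon(subject), "")[[1]]
  best <- -Inf
  for (qs in seq_along(q)) for (ss in seq_along(s)) {
    len_max <- min(length(q) - qs, length(s) - ss) + 1L
    sc <- 0
    for (l in seq_len(len_max)) {
      sc <- sc + if (q[qs + l - 1] == s[ss + l - 1]) match else mismatch
      if (sc > best) best <- sc
    }
  }
  best
}

# random proteoform on a random sequence, respecting site rules
random_proteoform <- function(n = 12) {
  aa <- names(residue_masses())
  seqv <- sample(aa, n, replace = TRUE)
  sequence <- paste(seqv, collapse = "")
  mods <- data.frame(site = integer(0), name = character(0))
  if (stats::runif(1) < 0.5) mods <- rbind(mods, data.frame(site = 0L, name = "ac"))
  ks <- which(seqv == "K")
  if (length(ks) && stats::runif(1) < 0.7) {
    k <- ks[sample.int(length(ks), 1)]
    mods <- rbind(mods, data.frame(site = k,
                                   name = sample(c("ac", "me1", "me2", "me3"), 1)))
  }
  ms <- setdiff(which(seqv == "M"), mods$site)
  if (length(ms) && stats::runif(1) < 0.3)
    mods <- rbind(mods, data.frame(site = ms[1], name = "ox"))
  proteoform(sequence, mods)
}
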