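# Shared fixtures and independent oracles used across the suite.

# Tiny two-subset dataset with hand-settable values.
toy_dataset <- function(values = NULL, study_id = "S1") {
  if (is.null(values)) {
    values <- matrix(c(10, 12, 14, 16,
                       4, 6, 8, 10,
                       100, 100, 100, 100),
                     nrow = 3, byrow = TRUE,
                     dimnames = list(c("GA", "GB", "GC"),
                                     paste0("s", 1:4)))
  }
  ann <- data.frame(sample_id = colnames(values), study_id = study_id,
                    platform_id = "P1",
                    subset = rep(c("classical", "nonclassical"),
                                 length.out = ncol(values)),
                    disease = "healthy", stringsAsFactors = FALSE)
  expression_dataset(values, ann)
}

# Pure-subset linear mean profiles with planted classical/nonclassical
# markers, for the profile-based simulators.
pure_profiles <- function(n_genes = 60, n_markers = 10, fold = 8,
                          base = 256) {
  genes <- sprintf("P%03d", seq_len(n_genes))
  cla <- setNames(rep(base, n_genes), genes)
  non <- cla
  cla[seq_len(n_markers)] <- base * fold
  non[n_markers + seq_len(n_markers)] <- base * fold
  list(classical = cla, nonclassical = non,
       classical_markers = genes[seq_len(n_markers)],
       nonclassical_markers = genes[n_markers + seq_len(n_markers)])
}

# Brute-force pre-ranked GSEA running-sum enumeration (independent of the
# package implementation).
es_brute <- function(ranking, set, p = 1) {
  s <- sort(ranking, decreasing = TRUE)
  hit <- names(s) %in% set
  nr <- sum(abs(s[hit])^p)
  N <- length(s); nh <- sum(hit)
  step <- ifelse(hit, abs(s)^p / nr, -1 / (N - nh))
  cs <- cumsum(step)
  cs[which.max(abs(cs))]
}

# Brute-force AUROC by enumeration of all positive-negative pairs.
auroc_brute <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Brute-force Benjamini-Hochberg step-up.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
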