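# shared fixtures: tiny cohorts and on-disk quantification files, built in code

toy_cohort <- function(stages = c("normal", "normal", "1", "1"),
                       types = rep("tissue", length(stages)),
                       p = 3, seed = 99) {
  set.seed(seed)
  m <- matrix(abs(rnorm(length(stages) * p, 5, 2)), length(stages), p,
              dimnames = list(paste0("s", seq_along(stages)),
                              sprintf("mir-%03d", seq_len(p))))
  mirna_cohort(m, stages, types)
}

# cohort with the study's printed group composition but few features
paper_shaped_cohort <- function(n_mirnas = 6) {
  cfg <- synthetic_config(n_mirnas = n_mirnas, effects = NULL, seed = 3)
  generate_cohort(cfg)$cohort
}

write_quant_fixture <- function(path, ids = c("mir-a", "mir-b", "mir-c"),
                                counts = c(10L, 20L, 0L),
                                rpm = c(1, 2, 0)) {
  df <- data.frame(miRNA_ID = ids, read_count = counts,
                   reads_per_million_miRNA_mapped = rpm)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# independent step-up BH oracle: adj_(k) = min over j >= k of min(1, m p_(j)/j)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (k in seq_len(m))
    adj[k] <- min(1, min(ps[k:m] * m / (k:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# exhaustive greedy MRMR oracle built directly on the set definitions,
# independent of the incremental bookkeeping in mrmr()
mrmr_oracle <- function(X, y, k, n_bins = 4) {
  Xd <- apply(X, 2, discretize, n_bins = n_bins)
  colnames(Xd) <- colnames(X)
  sel <- character(0)
  for (step in seq_len(k)) {
    cands <- setdiff(colnames(Xd), sel)
    scores <- vapply(cands, function(cand)
      miq_score(Xd, cand, sel, y), numeric(1))
    sel <- c(sel, cands[order(-scores, cands)][1])
  }
  sel
}
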