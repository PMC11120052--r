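#' Equal-frequency discretization
#'
#' Bins a numeric vector into `n_bins` quantile bins. Tied values always share
#' a bin; a constant vector collapses to a single bin and is flagged
#' uninformative via the `uninformative` attribute.
#'
#' @param values numeric vector.
#' @param n_bins number of bins, at least 2.
#' @return integer bin index vector (1-based) with attribute `uninformative`.
#' @export
discretize <- function(values, n_bins = 4) {
  if (n_bins < 2) stop("n_bins must be at least 2")
  if (any(!is.finite(values))) stop("values must be finite")
  br <- unique(stats::quantile(values, probs = seq_len(n_bins - 1) / n_bins,
                               names = FALSE, type = 7))
  bins <- findInterval(values, br, left.open = TRUE) + 1L
  # quantile breaks equal to the minimum can leave bin 1 empty; recompact
  bins <- as.integer(factor(bins))
  attr(bins, "uninformative") <- length(unique(bins)) < 2
  bins
}

#' Chi-square statistic of a contingency table
#'
#' Pearson's chi-square without continuity correction: sum of (O - E)^2 / E
#' with expected counts from the row/column margins. Zero-margin rows or
#' columns are dropped with a warning before computation.
#'
#' @param table matrix of nonnegative counts (expression bin x class).
#' @return list with `statistic`, `dof` and `p`.
#' @export
chi2_statistic <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be nonnegative")
  zr <- rowSums(table) == 0
  zc <- colSums(table) == 0
  if (any(zr) || any(zc)) {
    warning("dropping ", sum(zr), " zero-margin row(s) and ",
            sum(zc), " zero-margin column(s)")
    table <- table[!zr, !zc, drop = FALSE]
  }
  if (nrow(table) < 2 || ncol(table) < 2)
    return(list(statistic = 0, dof = 0L, p = 1))
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), dof = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Rank miRNAs by chi-square dependence on the class label
#'
#' Each feature is quantile-discretized, cross-tabulated against the class
#' label, and scored by the Pearson chi-square statistic; features are
#' returned in descending statistic order, ties broken lexicographically.
#' Constant (uninformative) features score 0.
#'
#' @param X numeric matrix, samples x features, with feature column names.
#' @param y class label vector (at least 2 classes present).
#' @param n_bins bins for [discretize()].
#' @return data.frame of class `feature_ranking` with columns `mirna_id`,
#'   `score` (the statistic) and `p`, ordered by rank.
#' @export
chi2_rank <- function(X, y, n_bins = 4) {
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2) stop("need at least 2 classes to rank")
  y <- droplevels(y)
  stats_p <- vapply(seq_len(ncol(X)), function(j) {
    b <- discretize(X[, j], n_bins)
    if (attr(b, "uninformative")) return(c(0, 1))
    r <- chi2_statistic(table(b, y))
    c(r$statistic, r$p)
  }, numeric(2))
  out <- data.frame(mirna_id = colnames(X),
                    score = stats_p[1, ], p = stats_p[2, ],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "method") <- "chi2"
  class(out) <- c("feature_ranking", "data.frame")
  out
}

#' @export
print.feature_ranking <- function(x, n = 10, ...) {
  cat("Feature ranking (", attr(x, "method"), "), ", nrow(x), " features\n",
      sep = "")
  print.data.frame(utils::head(x, n), digits = 4)
  invisible(x)
}

#' Top-k identifiers of a ranking
#' @param ranking a `feature_ranking` (or any data.frame with `mirna_id` in
#'   rank order).
#' @param k number of features.
#' @return character vector of at most `k` miRNA ids.
#' @export
top_features <- function(ranking, k) {
  if (k <= 0) stop("k must be positive")
  utils::head(ranking$mirna_id, k)
}
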