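#' Fold change between group means
#'
#' Ratio of mean tumor expression to mean normal expression. A zero tumor mean
#' over a positive normal mean is 0 (extreme down-regulation); a positive
#' tumor mean over a zero normal mean is `Inf` (extreme up-regulation); 0/0 is
#' undefined and returned as `NaN`.
#'
#' @param mean_tumor,mean_normal nonnegative group means (rpm); vectorized.
#' @return numeric fold change(s).
#' @export
fold_change <- function(mean_tumor, mean_normal) {
  if (any(!is.finite(mean_tumor)) || any(!is.finite(mean_normal)))
    stop("group means must be finite")
  if (any(mean_tumor < 0) || any(mean_normal < 0))
    stop("validation error: negative group mean")
  fc <- ifelse(mean_normal > 0, mean_tumor / mean_normal,
               ifelse(mean_tumor > 0, Inf, NaN))
  fc
}

#' Log2 fold change
#'
#' log base 2 of a positive fold change; a two-fold change maps to 1, a
#' four-fold change to 2. Callers must route fold change 0 to a `-Inf`
#' sentinel explicitly; this function rejects non-positive input.
#'
#' @param fc positive fold change(s).
#' @return numeric log2 fold change(s).
#' @export
log2_fold_change <- function(fc) {
  if (any(is.na(fc)) || any(fc <= 0))
    stop("domain error: fold change must be > 0")
  log2(fc)
}

#' Two-group differential-expression test
#'
#' Per-miRNA p-value for tumor vs normal. The default is the two-sided
#' rank-sum (Wilcoxon) test, exact for small untied samples, which is robust
#' to the heavy right skew of rpm values; alternatively a two-sample t-test on
#' log2(rpm + 1).
#'
#' @param tumor,normal numeric rpm vectors, at least 2 values each.
#' @param method `"ranksum"` (default) or `"t_log2"`.
#' @return two-sided p-value in [0, 1].
#' @export
de_test <- function(tumor, normal, method = c("ranksum", "t_log2")) {
  method <- match.arg(method)
  if (length(tumor) < 2) stop("tumor group needs at least 2 samples")
  if (length(normal) < 2) stop("normal group needs at least 2 samples")
  if (method == "ranksum") {
    if (stats::var(tumor) == 0 && stats::var(normal) == 0 &&
        tumor[1] == normal[1]) return(1)
    p <- suppressWarnings(stats::wilcox.test(tumor, normal)$p.value)
  } else {
    lt <- log2(tumor + 1); ln <- log2(normal + 1)
    if (stats::var(lt) == 0 && stats::var(ln) == 0)
      return(if (lt[1] == ln[1]) 1 else 0)
    p <- stats::t.test(lt, ln)$p.value
  }
  min(max(p, 0), 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: p-values are ranked ascending,
#' each is scaled by m/rank, and monotonicity is enforced from the largest
#' down; results are returned in the input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("validation error: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-stage differential expression table
#'
#' Contrasts tumor-tissue samples of one stage against normal-tissue samples,
#' one row per miRNA: group means, fold change, log2 fold change, p-value and
#' BH-adjusted p-value, and a direction call (`up` if the adjusted p is below
#' `alpha` and the fold change exceeds 1, `down` below 1, else `none`).
#'
#' @param cohort a filtered [mirna_cohort()].
#' @param stage tumor stage, one of "1".."4".
#' @param method test passed to [de_test()].
#' @param alpha significance level for the direction call (default 0.05).
#' @return data.frame of class `de_table`, one row per miRNA (column order of
#'   the cohort), with attribute `stage`.
#' @export
diff_expression <- function(cohort, stage, method = c("ranksum", "t_log2"),
                            alpha = 0.05) {
  stopifnot(inherits(cohort, "mirna_cohort"))
  method <- match.arg(method)
  stage <- normalize_stage(stage)
  if (!stage %in% TUMOR_STAGES) stop("stage must be one of 1..4")
  tum <- cohort$stage == stage & cohort$sample_type == "tissue"
  nor <- cohort$stage == "normal" & cohort$sample_type == "tissue"
  if (sum(tum) < 2) stop("fewer than 2 tumor samples for stage ", stage)
  if (sum(nor) < 2) stop("fewer than 2 normal samples")
  X_t <- cohort$expr[tum, , drop = FALSE]
  X_n <- cohort$expr[nor, , drop = FALSE]
  mt <- colMeans(X_t)
  mn <- colMeans(X_n)
  fc <- fold_change(mt, mn)
  l2 <- ifelse(is.nan(fc), NaN,
               ifelse(fc == 0, -Inf, ifelse(is.infinite(fc), Inf, log2(fc))))
  pv <- vapply(seq_len(ncol(X_t)),
               function(j) de_test(X_t[, j], X_n[, j], method), numeric(1))
  adj <- bh_adjust(pv)
  dir <- ifelse(is.nan(fc) | adj >= alpha, "none",
                ifelse(fc > 1, "up", ifelse(fc < 1, "down", "none")))
  out <- data.frame(mirna_id = colnames(cohort$expr),
                    mean_tumor = mt, mean_normal = mn,
                    fold_change = fc, log2_fc = l2,
                    p_value = pv, adj_p = adj, direction = dir,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "stage") <- stage
  attr(out, "method") <- method
  attr(out, "alpha") <- alpha
  class(out) <- c("de_table", "data.frame")
  out
}

#' @export
print.de_table <- function(x, ...) {
  cat("Differential expression, stage ", attr(x, "stage"),
      " tumor vs normal (", attr(x, "method"), "): ",
      nrow(x), " miRNAs, ", sum(x$direction == "up"), " up / ",
      sum(x$direction == "down"), " down at adj p < ", attr(x, "alpha"),
      "\n", sep = "")
  print.data.frame(utils::head(x[order(x$adj_p), ], 10), digits = 4)
  invisible(x)
}

#' Top dysregulated miRNAs from a DE table
#'
#' Candidates must satisfy `adj_p < alpha`. The up list takes the `k` largest
#' fold changes above 1 (an infinite fold change — tumor expression with a
#' zero normal mean — sorts above every finite one); the down list takes the
#' `k` smallest fold changes below 1. Ties break lexicographically by miRNA
#' id.
#'
#' @param de a `de_table` from [diff_expression()].
#' @param k list length (default 10).
#' @param alpha significance threshold on the adjusted p-value.
#' @return list with character vectors `up` and `down` (each at most `k`).
#' @export
rank_dysregulated <- function(de, k = 10, alpha = 0.05) {
  stopifnot(inherits(de, "de_table"))
  if (k <= 0) stop("k must be positive")
  sig <- de[!is.nan(de$fold_change) & de$adj_p < alpha, , drop = FALSE]
  up <- sig[sig$fold_change > 1, , drop = FALSE]
  up <- up[order(-up$fold_change, up$mirna_id), , drop = FALSE]
  down <- sig[sig$fold_change < 1, , drop = FALSE]
  down <- down[order(down$fold_change, down$mirna_id), , drop = FALSE]
  list(up = utils::head(up$mirna_id, k), down = utils::head(down$mirna_id, k))
}

#' Write a DE table as TSV
#'
#' @param de a `de_table`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_de_table <- function(de, path) {
  out <- de
  for (col in c("mean_tumor", "mean_normal", "fold_change", "log2_fc",
                "p_value", "adj_p"))
    out[[col]] <- sprintf("%.10g", out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}
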