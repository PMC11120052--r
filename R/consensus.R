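#' Consensus biomarkers: intersection of two top-k rankings
#'
#' The miRNAs present in the top `k` of both rankings (default k = 50),
#' ordered by the first ranking's rank. If either ranking is shorter than
#' `k`, `k` is clamped with a warning.
#'
#' @param r1,r2 `feature_ranking` objects (conventionally NCA and MRMR; the
#'   output order follows `r1`).
#' @param k list depth (default 50).
#' @param stage optional stage tag stored on the result.
#' @return object of class `consensus_set`: list with `common` (ordered
#'   miRNA ids), `k_used` and `stage`.
#' @export
intersect_top_k <- function(r1, r2, k = 50, stage = NA_character_) {
  if (k <= 0) stop("k must be positive")
  avail <- min(nrow(r1), nrow(r2))
  if (avail < k) {
    warning("rankings have only ", avail, " features; clamping k to ", avail)
    k <- avail
  }
  t1 <- utils::head(r1$mirna_id, k)
  t2 <- utils::head(r2$mirna_id, k)
  structure(list(common = t1[t1 %in% t2], k_used = k, stage = stage),
            class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat("Consensus set (top-", x$k_used, " intersection)",
      if (!is.na(x$stage)) paste0(", stage ", x$stage), ": ",
      length(x$common), " miRNAs\n", sep = "")
  if (length(x$common)) print(x$common)
  invisible(x)
}

#' Evaluate a consensus biomarker set
#'
#' Cross-validated stage-vs-normal accuracy restricted to the consensus
#' features (method tag `"common"`). An empty consensus yields an explicit
#' empty report with a warning rather than an error, since intersections can
#' legitimately be empty.
#'
#' @param cohort a filtered [mirna_cohort()].
#' @param consensus a [intersect_top_k()] result (with its `stage` set), or a
#'   character vector of miRNA ids together with `stage`.
#' @param stage tumor stage; defaults to the consensus set's stage tag.
#' @inheritParams cross_validate
#' @return a `stage_eval` report, or an empty report (`mean_accuracy = NA`)
#'   when the consensus is empty.
#' @export
evaluate_consensus <- function(cohort, consensus, stage = NULL,
                               classifier = "svm_linear", n_folds = 5,
                               seed = 1) {
  if (inherits(consensus, "consensus_set")) {
    feats <- consensus$common
    if (is.null(stage)) stage <- consensus$stage
  } else feats <- as.character(consensus)
  if (is.null(stage) || is.na(stage)) stop("stage must be supplied")
  if (length(feats) == 0) {
    warning("empty consensus set for stage ", stage, "; returning empty report")
    return(structure(list(fold_accuracies = numeric(0),
                          mean_accuracy = NA_real_,
                          confusion = c(tp = 0, tn = 0, fp = 0, fn = 0),
                          feature_set = character(0),
                          n_folds = 0L, method = "common", seed = seed),
                     class = "stage_eval"))
  }
  ds <- build_stage_dataset(cohort, stage)
  cross_validate(ds$X, ds$y, classifier, n_folds, seed,
                 feature_set = feats, method = "common")
}
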