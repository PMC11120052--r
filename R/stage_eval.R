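#' Build a stage-vs-normal binary dataset
#'
#' Positives are tumor-tissue samples of the requested stage, negatives are
#' normal-tissue samples; every other sample is excluded.
#'
#' @param cohort a [mirna_cohort()].
#' @param stage tumor stage "1".."4".
#' @return list with `X` (samples x miRNAs matrix) and `y` (factor with
#'   levels `normal`, `tumor`).
#' @export
build_stage_dataset <- function(cohort, stage) {
  stopifnot(inherits(cohort, "mirna_cohort"))
  stage <- normalize_stage(stage)
  if (!stage %in% TUMOR_STAGES) stop("stage must be one of 1..4")
  pos <- which(cohort$stage == stage & cohort$sample_type == "tissue")
  neg <- which(cohort$stage == "normal" & cohort$sample_type == "tissue")
  if (length(pos) == 0) stop("no tumor-tissue samples for stage ", stage)
  if (length(neg) == 0) stop("no normal-tissue samples in cohort")
  idx <- c(neg, pos)
  list(X = cohort$expr[idx, , drop = FALSE],
       y = factor(rep(c("normal", "tumor"), c(length(neg), length(pos))),
                  levels = c("normal", "tumor")))
}

#' Classification accuracy from confusion counts
#'
#' (TP + TN) / (TP + TN + FP + FN).
#'
#' @param tp,tn,fp,fn nonnegative counts.
#' @return accuracy in [0, 1].
#' @export
accuracy <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0)) stop("confusion counts must be nonnegative")
  tot <- sum(counts)
  if (tot == 0) stop("no evaluated samples")
  (tp + tn) / tot
}

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin, keeping per-fold class fractions within one sample of global
make_folds <- function(y, n_folds, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(factor(y))) {
    idx <- which(y == cl)
    fold[sample(idx)] <- rep(seq_len(n_folds), length.out = length(idx))
  }
  fold
}

# default maximum-margin linear classifier; features standardized on the
# training fold only (constant columns pass through unscaled)
svm_linear_spec <- function(cost = 1) {
  list(
    train = function(X, y) {
      ctr <- colMeans(X)
      scl <- apply(X, 2, stats::sd)
      scl[scl == 0] <- 1
      Xs <- scale(X, center = ctr, scale = scl)
      model <- e1071::svm(Xs, factor(y), kernel = "linear", cost = cost,
                          scale = FALSE)
      list(model = model, center = ctr, scale = scl)
    },
    predict = function(fit, X) {
      Xs <- scale(X, center = fit$center, scale = fit$scale)
      as.character(stats::predict(fit$model, Xs))
    })
}

resolve_classifier <- function(classifier) {
  if (is.character(classifier) && length(classifier) == 1) {
    if (classifier == "svm_linear") return(svm_linear_spec())
    stop("unknown classifier spec: ", classifier)
  }
  if (is.list(classifier) && is.function(classifier$train) &&
      is.function(classifier$predict)) return(classifier)
  stop("classifier must be \"svm_linear\" or a list(train=, predict=)")
}

#' Stratified k-fold cross-validated accuracy
#'
#' Splits the samples into stratified folds (default 5, i.e. 80% training /
#' 20% testing per iteration, every sample tested exactly once), trains the
#' classifier on each training portion and scores accuracy on the held-out
#' fold. If a feature-selection function is supplied it is re-run inside each
#' training fold, so selection never sees the test samples.
#'
#' If the smaller class cannot place at least 2 samples in every fold the
#' fold count is reduced automatically with a warning; a class smaller than
#' the (possibly reduced) fold count is an error.
#'
#' @param X samples x features matrix.
#' @param y binary labels (factor with 2 levels).
#' @param classifier `"svm_linear"` (default: linear maximum-margin, unit
#'   cost) or a `list(train = function(X, y), predict = function(fit, X))`.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed controlling the fold shuffle.
#' @param select optional `function(X_train, y_train) -> character` returning
#'   the feature ids to use; applied per fold.
#' @param feature_set optional fixed feature id subset (selection done once,
#'   outside the CV loop); ignored when `select` is given.
#' @param method label stored in the report (e.g. "NCA", "FC").
#' @return object of class `stage_eval`: `fold_accuracies`, `mean_accuracy`,
#'   `confusion` (summed counts), `feature_set` (fixed set or per-fold list),
#'   `n_folds`, `method`, `seed`.
#' @export
cross_validate <- function(X, y, classifier = "svm_linear", n_folds = 5,
                           seed = 1, select = NULL, feature_set = NULL,
                           method = "custom") {
  y <- factor(y)
  if (nlevels(droplevels(y)) != 2) stop("cross_validate needs binary labels")
  spec <- resolve_classifier(classifier)
  min_class <- min(table(y))
  if (min_class < n_folds)
    stop("smallest class has ", min_class, " samples, fewer than ", n_folds,
         " folds; use fewer folds")
  if (floor(min_class / n_folds) < 2 && n_folds > 2) {
    n_folds_new <- max(2, floor(min_class / 2))
    warning("reducing folds from ", n_folds, " to ", n_folds_new,
            " so every fold holds at least 2 samples of each class")
    n_folds <- n_folds_new
  }
  if (!is.null(feature_set) && is.null(select)) {
    missing <- setdiff(feature_set, colnames(X))
    if (length(missing)) stop("unknown feature(s): ",
                              paste(utils::head(missing, 5), collapse = ", "))
  }
  fold <- make_folds(y, n_folds, seed)
  accs <- numeric(n_folds)
  conf <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  per_fold_sets <- vector("list", n_folds)
  pos_level <- levels(y)[2]
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    feats <- if (!is.null(select)) {
      select(X[tr, , drop = FALSE], y[tr])
    } else if (!is.null(feature_set)) feature_set else colnames(X)
    if (length(feats) == 0) stop("empty feature set in fold ", f)
    per_fold_sets[[f]] <- feats
    fit <- spec$train(X[tr, feats, drop = FALSE], y[tr])
    pred <- spec$predict(fit, X[!tr, feats, drop = FALSE])
    truth <- as.character(y[!tr])
    tp <- sum(pred == pos_level & truth == pos_level)
    tn <- sum(pred != pos_level & truth != pos_level)
    fp <- sum(pred == pos_level & truth != pos_level)
    fn <- sum(pred != pos_level & truth == pos_level)
    conf <- conf + c(tp = tp, tn = tn, fp = fp, fn = fn)
    accs[f] <- accuracy(tp, tn, fp, fn)
  }
  structure(list(fold_accuracies = accs,
                 mean_accuracy = mean(accs),
                 confusion = conf,
                 feature_set = if (!is.null(select)) per_fold_sets
                               else if (!is.null(feature_set)) feature_set
                               else colnames(X),
                 n_folds = n_folds,
                 method = method,
                 seed = seed),
            class = "stage_eval")
}

#' @export
print.stage_eval <- function(x, ...) {
  cat("Cross-validated evaluation (", x$method, "), ", x$n_folds,
      " folds\n", sep = "")
  cat("fold accuracies:", paste(sprintf("%.3f", x$fold_accuracies),
                                collapse = " "), "\n")
  cat("mean accuracy:", sprintf("%.4f", x$mean_accuracy), "\n")
  invisible(x)
}

#' Accuracy of the combined up + down dysregulated feature set
#'
#' Evaluates the union of the up- and down-regulated lists from
#' [rank_dysregulated()] for one stage (duplicates used once).
#'
#' @param cohort a filtered [mirna_cohort()].
#' @param stage tumor stage "1".."4".
#' @param up,down character vectors of miRNA ids.
#' @inheritParams cross_validate
#' @return a `stage_eval` report (method `"FC"`).
#' @export
combined_accuracy <- function(cohort, stage, up, down,
                              classifier = "svm_linear", n_folds = 5,
                              seed = 1) {
  feats <- unique(c(up, down))
  if (length(feats) == 0) stop("empty union of up- and down-regulated lists")
  ds <- build_stage_dataset(cohort, stage)
  cross_validate(ds$X, ds$y, classifier, n_folds, seed,
                 feature_set = feats, method = "FC")
}
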