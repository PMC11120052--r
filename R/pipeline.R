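#' Configure an end-to-end pipeline run
#'
#' Collects every knob of the staging pipeline: the input cohort (a synthetic
#' config, or expression + label file paths), the feature-selection methods to
#' run, significance and list-length settings, NCA and mutual-information
#' estimator options, and cross-validation settings. One global seed fans out
#' to labeled sub-seeds (generator, per-stage/method CV shuffles) so modules
#' are independently re-runnable yet reproducible.
#'
#' @param mode `"synthetic"` (default) or `"files"`.
#' @param synthetic a [synthetic_config()]; used when `mode = "synthetic"`.
#' @param expr_path,labels_path cohort files for `mode = "files"` (layout of
#'   [write_cohort()]).
#' @param methods subset of `c("FC", "chi2", "NCA", "MRMR")`.
#' @param alpha significance level for the DE direction calls.
#' @param k_de up/down list length (default 10).
#' @param k_eval features per method used for classification (default 10).
#' @param k_consensus ranking depth intersected for consensus biomarkers
#'   (default 50).
#' @param de_method test for [de_test()].
#' @param nca list of [nca()] arguments (sigma, lambda, max_iter, tol,
#'   transform).
#' @param n_bins equal-frequency bins shared by the chi-square and
#'   mutual-information estimators.
#' @param mi_base `"bits"` or `"nats"`.
#' @param n_folds cross-validation folds (default 5).
#' @param selection `"per_fold"` (default; NCA/MRMR/chi-square selection is
#'   re-run inside each training fold, avoiding selection leakage) or
#'   `"once"` (select on the full stage dataset, then cross-validate).
#' @param seed global integer seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"),
                       synthetic = synthetic_config(),
                       expr_path = NULL, labels_path = NULL,
                       methods = c("FC", "chi2", "NCA", "MRMR"),
                       alpha = 0.05, k_de = 10, k_eval = 10, k_consensus = 50,
                       de_method = "ranksum",
                       nca = list(sigma = 1, lambda = NULL, max_iter = 60,
                                  tol = 1e-6, transform = "zscore"),
                       n_bins = 4, mi_base = "bits",
                       n_folds = 5,
                       selection = c("per_fold", "once"),
                       seed = 1L) {
  mode <- match.arg(mode)
  selection <- match.arg(selection)
  methods <- match.arg(methods, several.ok = TRUE)
  if (mode == "files" && (is.null(expr_path) || is.null(labels_path)))
    stop("config error: mode \"files\" requires expr_path and labels_path")
  if (mode == "synthetic" && !inherits(synthetic, "synthetic_config"))
    stop("config error: `synthetic` must be a synthetic_config")
  stopifnot(alpha >= 0, alpha <= 1, k_de >= 1, k_eval >= 1, k_consensus >= 1,
            n_folds >= 2)
  structure(list(mode = mode, synthetic = synthetic,
                 expr_path = expr_path, labels_path = labels_path,
                 methods = methods, alpha = alpha,
                 k_de = k_de, k_eval = k_eval, k_consensus = k_consensus,
                 de_method = de_method, nca = nca,
                 n_bins = n_bins, mi_base = mi_base,
                 n_folds = n_folds, selection = selection,
                 seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass_deep(config), tmp, auto_unbox = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else x
}

write_report_table <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_md5: ", hash), con)
  num <- vapply(df, is.numeric, logical(1))
  for (col in names(df)[num]) df[[col]] <- sprintf("%.10g", df[[col]])
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
}

# selection closures used inside each CV training fold
make_selector <- function(method, config) {
  k <- config$k_eval
  switch(method,
    NCA = function(X, y) {
      fit <- do.call(nca, c(list(X = X, y = y), config$nca))
      top_features(nca_rank(fit), k)
    },
    MRMR = function(X, y)
      mrmr(X, y, k = min(k, ncol(X)), n_bins = config$n_bins,
           base = config$mi_base)$mirna_id,
    chi2 = function(X, y)
      top_features(chi2_rank(X, y, n_bins = config$n_bins), k),
    stop("no selector for method ", method))
}

#' Run the full staging pipeline
#'
#' Executes, per tumor stage: the fold-change differential-expression table
#' and up/down lists, feature rankings for the requested methods, stratified
#' cross-validated stage-vs-normal accuracy per method, and (when both NCA
#' and MRMR are requested) the top-k consensus biomarkers and their accuracy.
#' All reports are written as TSV files carrying the configuration hash, plus
#' a machine-readable `provenance.json`; identical config + seed reproduces
#' byte-identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory reports: `cohort` (filtered),
#'   `de` (per-stage `de_table`s), `rankings`, `evals` (accuracy table as
#'   data.frame), `consensus`, `trend`, and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)

  cohort <- if (config$mode == "synthetic") {
    cfg <- config$synthetic
    cfg$seed <- config$seed
    generate_cohort(cfg)$cohort
  } else {
    read_cohort(config$expr_path, config$labels_path)
  }
  filtered <- filter_cohort(cohort)
  message("cohort: ", n_samples(cohort), " samples, ", n_samples(filtered),
          " retained after Stage X / blood exclusions")

  methods <- config$methods
  de_list <- list()
  rankings <- list()
  consensus <- list()
  acc_rows <- list()

  add_row <- function(stage, method, ev) {
    accs <- ev$fold_accuracies
    length(accs) <- 5  # pad with NA if folds were reduced
    acc_rows[[length(acc_rows) + 1]] <<- data.frame(
      stage = stage, method = method,
      n_features = if (is.list(ev$feature_set))
        length(ev$feature_set[[1]]) else length(ev$feature_set),
      fold1 = accs[1], fold2 = accs[2], fold3 = accs[3],
      fold4 = accs[4], fold5 = accs[5],
      mean_accuracy = ev$mean_accuracy,
      stringsAsFactors = FALSE)
  }

  for (si in seq_along(TUMOR_STAGES)) {
    stage <- TUMOR_STAGES[si]
    ds <- build_stage_dataset(filtered, stage)
    cv_seed <- function(m) config$seed + 100L * si + m

    if ("FC" %in% methods) {
      t0 <- proc.time()[3]
      de <- diff_expression(filtered, stage, method = config$de_method,
                            alpha = config$alpha)
      de_list[[stage]] <- de
      write_de_table(de, file.path(out_dir, paste0("de_stage", stage, ".tsv")))
      lists <- rank_dysregulated(de, k = config$k_de, alpha = config$alpha)
      for (side in c("up", "down")) {
        feats <- lists[[side]]
        if (length(feats))
          add_row(stage, paste0("FC_", side),
                  cross_validate(ds$X, ds$y, n_folds = config$n_folds,
                                 seed = cv_seed(1L), feature_set = feats,
                                 method = paste0("FC_", side)))
      }
      if (length(unique(c(lists$up, lists$down))))
        add_row(stage, "FC_combined",
                combined_accuracy(filtered, stage, lists$up, lists$down,
                                  n_folds = config$n_folds, seed = cv_seed(1L)))
      message(sprintf("stage %s FC: %.1fs", stage, proc.time()[3] - t0))
    }

    for (m in intersect(c("chi2", "NCA", "MRMR"), methods)) {
      t0 <- proc.time()[3]
      rk <- switch(m,
        chi2 = chi2_rank(ds$X, ds$y, n_bins = config$n_bins),
        NCA = nca_rank(do.call(nca, c(list(X = ds$X, y = ds$y), config$nca))),
        MRMR = mrmr(ds$X, ds$y,
                    k = min(config$k_consensus, ncol(ds$X)),
                    n_bins = config$n_bins, base = config$mi_base))
      rankings[[stage]][[m]] <- rk
      write_report_table(
        utils::head(as.data.frame(rk)[, c("mirna_id", "score")],
                    config$k_consensus),
        file.path(out_dir, paste0("ranking_", tolower(m), "_stage", stage,
                                  ".tsv")), hash)
      ev <- if (config$selection == "per_fold") {
        cross_validate(ds$X, ds$y, n_folds = config$n_folds,
                       seed = cv_seed(match(m, c("chi2", "NCA", "MRMR")) + 1L),
                       select = make_selector(m, config), method = m)
      } else {
        cross_validate(ds$X, ds$y, n_folds = config$n_folds,
                       seed = cv_seed(match(m, c("chi2", "NCA", "MRMR")) + 1L),
                       feature_set = top_features(rk, config$k_eval),
                       method = m)
      }
      add_row(stage, m, ev)
      message(sprintf("stage %s %s: %.1fs", stage, m, proc.time()[3] - t0))
    }

    if (all(c("NCA", "MRMR") %in% methods)) {
      cs <- intersect_top_k(rankings[[stage]][["NCA"]],
                            rankings[[stage]][["MRMR"]],
                            k = config$k_consensus, stage = stage)
      consensus[[stage]] <- cs
      write_report_table(
        data.frame(rank = seq_along(cs$common), mirna_id = cs$common),
        file.path(out_dir, paste0("consensus_stage", stage, ".tsv")), hash)
      ev <- suppressWarnings(
        evaluate_consensus(filtered, cs, n_folds = config$n_folds,
                           seed = cv_seed(9L)))
      add_row(stage, "common", ev)
    }
  }

  acc <- do.call(rbind, acc_rows)
  write_report_table(acc, file.path(out_dir, "accuracy_table.tsv"), hash)

  trend <- NULL
  if ("FC" %in% methods) {
    trend <- report_gene_count_trend(de_list, alpha = config$alpha)
    write_report_table(trend, file.path(out_dir, "gene_count_trend.tsv"), hash)
  }

  prov <- list(config = unclass_deep(config), config_md5 = hash,
               seed = config$seed,
               package = as.character(utils::packageVersion("stagemiR")))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(cohort = filtered, de = de_list, rankings = rankings,
                 evals = acc, consensus = consensus, trend = trend,
                 out_dir = out_dir))
}

#' Significant up/down gene counts per stage
#'
#' Counts, for each of the four stages, the miRNAs called up- and
#' down-regulated at `adj_p < alpha`, summarizing how the number of
#' dysregulated genes moves across stages. The direction of the trend is
#' data-dependent and is reported, not asserted.
#'
#' @param de_list named list of `de_table`s with entries "1".."4".
#' @param alpha significance threshold on the adjusted p-value.
#' @return data.frame with columns `stage`, `n_up`, `n_down`.
#' @export
report_gene_count_trend <- function(de_list, alpha = 0.05) {
  miss <- setdiff(TUMOR_STAGES, names(de_list))
  if (length(miss))
    stop("missing DE table(s) for stage(s): ", paste(miss, collapse = ", "))
  rows <- lapply(TUMOR_STAGES, function(s) {
    de <- de_list[[s]]
    sig <- !is.nan(de$fold_change) & de$adj_p < alpha
    data.frame(stage = s,
               n_up = sum(sig & de$fold_change > 1),
               n_down = sum(sig & de$fold_change < 1))
  })
  do.call(rbind, rows)
}
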