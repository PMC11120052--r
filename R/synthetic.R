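#' Planted dysregulation effects
#'
#' Describes which miRNAs are truly differentially expressed in which tumor
#' stage, and by how much. A fold change above 1 is up-regulation in tumor
#' tissue of that stage, below 1 down-regulation.
#'
#' @param mirna_id character vector of miRNA identifiers.
#' @param stage stage each effect applies to ("1".."4"); recycled.
#' @param fold_change positive fold changes (tumor mean / normal mean);
#'   recycled.
#' @return data.frame with columns `mirna_id`, `stage`, `fold_change`,
#'   `direction`.
#' @export
planted_effects <- function(mirna_id, stage, fold_change) {
  df <- data.frame(mirna_id = as.character(mirna_id),
                   stage = as.character(stage),
                   fold_change = as.numeric(fold_change),
                   stringsAsFactors = FALSE)
  if (!all(df$stage %in% TUMOR_STAGES))
    stop("effect stage must be one of ", paste(TUMOR_STAGES, collapse = ", "))
  if (any(!is.finite(df$fold_change)) || any(df$fold_change <= 0))
    stop("fold_change must be positive and finite")
  if (any(df$fold_change == 1))
    stop("fold_change 1 is not an effect")
  if (anyDuplicated(df[, c("mirna_id", "stage")]))
    stop("duplicate (mirna_id, stage) effect")
  df$direction <- ifelse(df$fold_change > 1, "up", "down")
  df
}

default_effects <- function(n_mirnas = 1881L, n_up = 10L, n_down = 10L,
                            fc_up = 4, fc_down = 0.25) {
  # shrink the per-stage marker count when the feature space is too small to
  # host disjoint markers for all four stages
  avail <- n_mirnas %/% (4L * (n_up + n_down))
  if (avail < 1) {
    n_each <- n_mirnas %/% 8L
    if (n_each < 1) return(NULL)
    n_up <- n_down <- n_each
  }
  ids <- mirna_ids(n_mirnas)
  out <- NULL
  idx <- 1L
  for (s in TUMOR_STAGES) {
    eff <- planted_effects(ids[idx:(idx + n_up + n_down - 1L)], s,
                           c(rep(fc_up, n_up), rep(fc_down, n_down)))
    out <- rbind(out, eff)
    idx <- idx + n_up + n_down
  }
  out
}

mirna_ids <- function(p) sprintf("mir-%04d", seq_len(p))

#' Configure a synthetic miRNA cohort
#'
#' Defines the study conditions the generator emulates: the group composition
#' of a breast-cancer miRNA-seq cohort (113 normal tissue, 111/350/131/11
#' tumor tissue in stages 1-4, 5 unassessable Stage X tissue, 486
#' blood-derived samples; 1881 miRNA features), a heavy-tailed log-normal
#' baseline for rpm expression, multiplicative per-sample noise, and a set of
#' planted stage-specific dysregulated miRNAs.
#'
#' By default each stage carries 10 up-regulated (fold change 4) and 10
#' down-regulated (fold change 0.25) planted markers on disjoint miRNAs,
#' mirroring the 10+10 report shape of a per-stage differential-expression
#' table.
#'
#' @param n_normal,n_stage,n_stage_x,n_blood group sizes; `n_stage` is a
#'   length-4 vector for stages 1-4.
#' @param n_mirnas number of miRNA features.
#' @param baseline_log_mean,baseline_log_sd mean and sd (natural-log scale) of
#'   the per-miRNA baseline expression draw.
#' @param noise_log_sd sd (natural-log scale) of the multiplicative per-sample
#'   noise.
#' @param effects data.frame from [planted_effects()], or `NULL` for an
#'   effect-free (null) cohort.
#' @param seed integer seed; the same config generates bit-identical cohorts.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_normal = 113L,
                             n_stage = c(111L, 350L, 131L, 11L),
                             n_stage_x = 5L,
                             n_blood = 486L,
                             n_mirnas = 1881L,
                             baseline_log_mean = 2,
                             baseline_log_sd = 2,
                             noise_log_sd = 0.6,
                             effects = default_effects(n_mirnas),
                             seed = 1L) {
  stopifnot(length(n_stage) == 4, all(n_stage >= 0), n_normal >= 0,
            n_stage_x >= 0, n_blood >= 0, n_mirnas >= 1,
            baseline_log_sd > 0, noise_log_sd > 0)
  ids <- mirna_ids(n_mirnas)
  if (!is.null(effects) && nrow(effects)) {
    unknown <- setdiff(effects$mirna_id, ids)
    if (length(unknown))
      stop("config error: effect references unknown miRNA(s): ",
           paste(utils::head(unknown, 5), collapse = ", "))
  }
  structure(list(n_normal = as.integer(n_normal),
                 n_stage = as.integer(n_stage),
                 n_stage_x = as.integer(n_stage_x),
                 n_blood = as.integer(n_blood),
                 n_mirnas = as.integer(n_mirnas),
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 noise_log_sd = noise_log_sd,
                 effects = effects,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic labeled cohort with ground truth
#'
#' Each miRNA gets a log-normal baseline mean; each sample observes that mean
#' times log-normal noise. For a planted effect, tumor-tissue samples of the
#' effect's stage have the miRNA's mean multiplied by its fold change. Blood
#' samples and Stage X samples are generated signal-free (normal-tissue
#' means), encoding the observation that blood miRNA composition does not
#' separate tumor from normal.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `cohort` (a [mirna_cohort()]) and `truth` (list
#'   with the `effects` table and `per_stage`, the per-stage sets of truly
#'   informative miRNA ids).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  stage_lab <- c(rep("normal", config$n_normal),
                 rep(TUMOR_STAGES, config$n_stage),
                 rep("X", config$n_stage_x),
                 rep(TUMOR_STAGES, length.out = config$n_blood))
  type_lab <- c(rep("tissue", config$n_normal + sum(config$n_stage) + config$n_stage_x),
                rep("blood", config$n_blood))
  n <- length(stage_lab)
  p <- config$n_mirnas
  ids <- mirna_ids(p)

  baseline <- exp(stats::rnorm(p, config$baseline_log_mean, config$baseline_log_sd))
  # multiplier[i, r]: planted fold change for tumor-tissue samples only
  dn <- list(if (n > 0) paste0("sample-", seq_len(n)) else NULL, ids)
  expr <- matrix(stats::rlnorm(n * p, meanlog = 0, sdlog = config$noise_log_sd),
                 n, p, dimnames = dn)
  expr <- sweep(expr, 2, baseline, `*`)
  eff <- config$effects
  if (!is.null(eff) && nrow(eff)) {
    for (k in seq_len(nrow(eff))) {
      rows <- which(stage_lab == eff$stage[k] & type_lab == "tissue")
      col <- match(eff$mirna_id[k], ids)
      expr[rows, col] <- expr[rows, col] * eff$fold_change[k]
    }
  }
  cohort <- mirna_cohort(expr, stage_lab, type_lab)
  per_stage <- lapply(TUMOR_STAGES, function(s) {
    if (is.null(eff)) character(0) else sort(eff$mirna_id[eff$stage == s])
  })
  names(per_stage) <- TUMOR_STAGES
  list(cohort = cohort,
       truth = list(effects = eff, per_stage = per_stage))
}

#' Generate an effect-free (null) cohort
#'
#' Convenience wrapper: same generative model with no planted effects, so the
#' labels carry no expression signal. Used for false-positive-rate and
#' chance-level-accuracy calibration.
#'
#' @param config a [synthetic_config()]; its `effects` are ignored.
#' @return a [mirna_cohort()].
#' @export
effect_free_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  config$effects <- NULL
  generate_cohort(config)$cohort
}
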