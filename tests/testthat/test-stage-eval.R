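test_that("stage datasets contrast the requested stage against normals", {
  co <- paper_shaped_cohort()
  kept <- filter_cohort(co)
  ds1 <- build_stage_dataset(kept, "1")
  expect_equal(as.integer(table(ds1$y)), c(113L, 111L))
  ds4 <- build_stage_dataset(kept, "4")
  expect_equal(sum(ds4$y == "tumor"), 11)
  expect_equal(sum(ds4$y == "normal"), 113)
  nonorm <- kept[kept$stage != "normal"]
  expect_error(build_stage_dataset(nonorm, "1"), "normal")
})

test_that("accuracy implements (TP+TN)/total with its edge cases", {
  expect_equal(accuracy(9, 9, 1, 1), 0.9)
  expect_equal(accuracy(7, 0, 0, 0), 1)
  expect_equal(accuracy(0, 0, 5, 5), 0)
  expect_error(accuracy(0, 0, 0, 0), "no evaluated")
  expect_error(accuracy(-1, 1, 1, 1), "nonnegative")
  # label-flip symmetry
  set.seed(3)
  for (i in 1:5) {
    cts <- rpois(4, 5) + 1
    expect_equal(accuracy(cts[1], cts[2], cts[3], cts[4]),
                 accuracy(cts[2], cts[1], cts[4], cts[3]))
  }
})

test_that("folds partition samples with stratified class balance", {
  set.seed(7)
  y <- factor(rep(c("normal", "tumor"), c(37, 23)))
  fold <- stagemiR:::make_folds(y, 5, seed = 1)
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(length(fold), 60)
  # disjoint cover: every sample in exactly one fold
  expect_equal(sum(table(fold)), 60)
  global_frac <- mean(y == "tumor")
  for (f in 1:5) {
    n_f <- sum(fold == f)
    pos_f <- sum(y[fold == f] == "tumor")
    expect_lte(abs(pos_f - global_frac * n_f), 1)
  }
  # deterministic under seed
  expect_identical(fold, stagemiR:::make_folds(y, 5, seed = 1))
})

test_that("cross-validation is deterministic and guards small strata", {
  set.seed(10)
  X <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- factor(rep(c("normal", "tumor"), each = 20))
  X[y == "tumor", 1] <- X[y == "tumor", 1] + 3
  e1 <- cross_validate(X, y, seed = 4)
  e2 <- cross_validate(X, y, seed = 4)
  expect_identical(e1$fold_accuracies, e2$fold_accuracies)
  expect_equal(e1$mean_accuracy, mean(e1$fold_accuracies))
  expect_equal(sum(e1$confusion), 40)   # every sample tested exactly once
  # class smaller than the fold count is an error
  ys <- factor(rep(c("normal", "tumor"), c(36, 4)))
  expect_error(cross_validate(X, ys, n_folds = 5), "fewer")
  # class that cannot give every fold 2 samples reduces the fold count
  ym <- factor(rep(c("normal", "tumor"), c(33, 7)))
  expect_warning(em <- cross_validate(X, ym, n_folds = 5), "reducing folds")
  expect_equal(em$n_folds, 3)
})

test_that("separable planted data is classified nearly perfectly", {
  ids <- sprintf("mir-%04d", 1:10)
  cfg <- synthetic_config(n_normal = 100, n_stage = c(100, 0, 0, 0),
                          n_stage_x = 0, n_blood = 0, n_mirnas = 50,
                          effects = planted_effects(ids, "1", rep(8, 10)),
                          seed = 14)
  ds <- build_stage_dataset(generate_cohort(cfg)$cohort, "1")
  ev <- cross_validate(ds$X, ds$y, seed = 1, feature_set = ids)
  expect_gte(ev$mean_accuracy, 0.95)
})

test_that("label-shuffled data scores near the majority-class rate", {
  # near-balanced contrast, mirroring the 113-normal / 111-stage-1 design
  accs <- numeric(12)
  for (i in seq_along(accs)) {
    cfg <- synthetic_config(n_normal = 25, n_stage = c(25, 0, 0, 0),
                            n_stage_x = 0, n_blood = 0, n_mirnas = 30,
                            effects = NULL, seed = 600 + i)
    ds <- build_stage_dataset(generate_cohort(cfg)$cohort, "1")
    set.seed(i)
    y_shuf <- sample(ds$y)
    accs[i] <- cross_validate(ds$X, y_shuf, seed = i)$mean_accuracy
  }
  majority <- 0.5
  se <- sd(accs) / sqrt(length(accs))
  expect_lte(abs(mean(accs) - majority), 3 * se + 0.02)
})

test_that("per-fold selection uses only training samples", {
  seen <- list()
  sel_spy <- function(X, y) {
    seen[[length(seen) + 1]] <<- nrow(X)
    colnames(X)[1:2]
  }
  set.seed(2)
  X <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- factor(rep(c("normal", "tumor"), each = 20))
  ev <- cross_validate(X, y, seed = 3, select = sel_spy)
  expect_equal(length(seen), 5)
  expect_true(all(unlist(seen) == 32))   # 80% of 40 per training fold
  expect_true(all(vapply(ev$feature_set, length, integer(1)) == 2))
})

test_that("combined up+down lists evaluate their union once", {
  ids_up <- sprintf("mir-%04d", 1:5)
  ids_down <- sprintf("mir-%04d", 6:10)
  cfg <- synthetic_config(n_normal = 60, n_stage = c(60, 0, 0, 0),
                          n_stage_x = 0, n_blood = 0, n_mirnas = 40,
                          effects = planted_effects(c(ids_up, ids_down), "1",
                                                    c(rep(6, 5), rep(1 / 6, 5))),
                          seed = 15)
  co <- generate_cohort(cfg)$cohort
  both <- combined_accuracy(co, "1", ids_up, ids_down, seed = 2)
  up_only <- combined_accuracy(co, "1", ids_up, character(0), seed = 2)
  expect_gte(both$mean_accuracy, up_only$mean_accuracy - 0.02)
  # duplicates across the lists collapse
  dup <- combined_accuracy(co, "1", ids_up, ids_up, seed = 2)
  expect_equal(length(dup$feature_set), 5)
  expect_identical(dup$fold_accuracies, up_only$fold_accuracies)
  expect_error(combined_accuracy(co, "1", character(0), character(0)),
               "empty")
})
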