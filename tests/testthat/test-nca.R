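test_that("weighted distance and kernel evaluate their closed forms", {
  expect_equal(nca_distance(c(0, 0), c(1, 1), c(2, 1)), 5)  # 4*1 + 1*1
  expect_equal(nca_distance(c(1, 2), c(1, 2), rnorm(2)), 0)
  expect_equal(nca_distance(c(0, 3), c(2, 0), c(0, 0)), 0)
  expect_error(nca_distance(1:2, 1:3, 1:2), "equal length")
  expect_equal(nca_kernel(0), 1)
  expect_equal(nca_kernel(log(2), sigma = 1), 0.5)
  z <- sort(runif(10, 0, 5))
  expect_true(all(diff(nca_kernel(z)) < 0))    # strictly decreasing
})

test_that("reference probabilities are row-stochastic softmax similarities", {
  set.seed(2)
  X <- matrix(rnorm(15), 5, 3)
  P <- nca_reference_prob(X, w = rep(1, 3))
  expect_equal(unname(rowSums(P)), rep(1, 5), tolerance = 1e-12)
  expect_equal(unname(diag(P)), rep(0, 5))
  # w = 0 collapses all distances: uniform over the other samples
  P0 <- nca_reference_prob(matrix(rnorm(6), 3, 2), w = c(0, 0))
  expect_equal(unname(P0[1, 2:3]), c(0.5, 0.5))
  # one neighbor at distance 0, one 50 apart: near-certain reference choice
  X2 <- matrix(c(0, 0, 50), 3, 1)
  P2 <- nca_reference_prob(X2, w = 1)
  expect_equal(P2[1, 2], 1, tolerance = 1e-20)
  expect_equal(P2[1, 3], exp(-50) / (1 + exp(-50)), tolerance = 1e-25)
  expect_error(nca_reference_prob(matrix(1, 1, 1), 1), "2 samples")
})

test_that("leave-one-out probabilities follow the same-class mass", {
  X <- matrix(rnorm(8), 4, 2)
  P <- nca_reference_prob(X, w = c(0, 0))
  # two samples per class, uniform reference: one of three others matches
  expect_equal(nca_loo_prob(P, c("a", "a", "b", "b")), rep(1 / 3, 4))
  expect_equal(nca_loo_prob(P, rep("a", 4)), rep(1, 4))
  expect_equal(nca_loo_prob(P, c("a", "b", "b", "b"))[1], 0)
})

test_that("objective at w = 0 equals the mean same-class fraction", {
  X <- matrix(rnorm(8), 4, 2)
  expect_equal(nca_objective(X, c("a", "a", "b", "b"), c(0, 0)), 1 / 3)
  # lambda = 0: objective is exactly mean(pi)
  set.seed(3)
  X2 <- matrix(rnorm(12), 6, 2)
  y2 <- rep(c("a", "b"), 3)
  w <- rnorm(2)
  P <- nca_reference_prob(X2, w)
  expect_equal(nca_objective(X2, y2, w), mean(nca_loo_prob(P, y2)))
})

test_that("analytic gradient matches central finite differences", {
  worst <- 0
  for (i in 1:25) {
    set.seed(i)
    n <- sample(4:12, 1); p <- sample(2:6, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- sample(c("a", "b", "c"), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c("a", "b")
    w <- rnorm(p); lam <- runif(1)
    g <- nca_gradient(X, y, w, sigma = 1, lambda = lam)
    h <- 1e-5
    fd <- vapply(seq_len(p), function(r) {
      e <- rep(0, p); e[r] <- h
      loss <- function(w) 1 - nca_objective(X, y, w, 1, lam)
      (loss(w + e) - loss(w - e)) / (2 * h)
    }, numeric(1))
    worst <- max(worst, max(abs(g - fd) / pmax(abs(fd), 1e-6)))
  }
  expect_lte(worst, 1e-5)
})

test_that("objective is invariant under sign flips of any weight", {
  set.seed(9)
  X <- matrix(rnorm(20), 5, 4)
  y <- c("a", "a", "b", "b", "a")
  w <- rnorm(4)
  base <- nca_objective(X, y, w, lambda = 0.3)
  for (r in 1:4) {
    wf <- w; wf[r] <- -wf[r]
    expect_equal(nca_objective(X, y, wf, lambda = 0.3), base)
  }
})

test_that("the solver is deterministic, monotone, and shrinks under heavy lambda", {
  set.seed(5)
  X <- cbind(sig = c(rnorm(15, 0), rnorm(15, 4)), n1 = rnorm(30),
             n2 = rnorm(30))
  y <- rep(c("a", "b"), each = 15)
  f1 <- nca(X, y, max_iter = 40)
  f2 <- nca(X, y, max_iter = 40)
  expect_identical(f1$w, f2$w)
  expect_true(all(diff(f1$objective_trace) <= 1e-12))
  # heavy regularization drives every weight to ~0
  fh <- nca(X, y, lambda = 1e3, max_iter = 200)
  expect_lt(max(abs(fh$w)), 1e-2)
  expect_error(nca(X, rep("a", 30)), "2 classes")
})

test_that("an informative feature earns the strictly largest weight", {
  set.seed(6)
  n <- 60
  X <- cbind(matrix(rnorm(n * 9), n, 9),
             info = c(rnorm(n / 2, -2), rnorm(n / 2, 2)))
  colnames(X) <- c(paste0("noise", 1:9), "info")
  y <- rep(c("a", "b"), each = n / 2)
  fit <- nca(X, y, max_iter = 60)
  w2 <- coef(fit)^2
  expect_equal(names(which.max(w2)), "info")
  expect_gt(w2["info"], max(w2[names(w2) != "info"]))
})

test_that("weight ranking orders by squared magnitude with stable ties", {
  fit <- structure(list(w = c(`mir-b` = 3, `mir-a` = -1, `mir-c` = 0)),
                   class = "nca")
  rk <- nca_rank(fit, k = 2)
  expect_equal(rk$mirna_id, c("mir-b", "mir-a"))
  fit0 <- structure(list(w = c(`mir-b` = 0, `mir-a` = 0)), class = "nca")
  rk0 <- nca_rank(fit0)
  expect_true(attr(rk0, "degenerate"))
  expect_equal(rk0$mirna_id, c("mir-a", "mir-b"))  # lexicographic fallback
  expect_error(nca_rank(fit, k = 0), "positive")
})

test_that("NCA recovers most planted markers on a synthetic stage", {
  ids <- sprintf("mir-%04d", 1:10)
  cfg <- synthetic_config(n_normal = 80, n_stage = c(80, 0, 0, 0),
                          n_stage_x = 0, n_blood = 0, n_mirnas = 200,
                          effects = planted_effects(ids, "1", rep(4, 10)),
                          seed = 11)
  ds <- build_stage_dataset(generate_cohort(cfg)$cohort, "1")
  fit <- nca(ds$X, ds$y, max_iter = 60)
  top20 <- top_features(nca_rank(fit), 20)
  expect_gte(sum(ids %in% top20), 8)
})
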