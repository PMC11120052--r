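#' Weighted feature distance
#'
#' The NCA metric: d_w(x_i, x_j) = sum_r w_r^2 |x_ir - x_jr|. Weights enter
#' squared, so the metric is invariant to their sign and always nonnegative.
#'
#' @param xi,xj numeric feature vectors of equal length.
#' @param w weight vector of the same length.
#' @return nonnegative distance.
#' @export
nca_distance <- function(xi, xj, w) {
  if (length(xi) != length(xj) || length(xi) != length(w))
    stop("xi, xj and w must have equal length")
  sum(w^2 * abs(xi - xj))
}

#' Distance-to-similarity kernel
#'
#' k(z) = exp(-z / sigma): maps a distance to a similarity in (0, 1],
#' strictly decreasing, 1 at distance 0.
#'
#' @param z nonnegative distance(s).
#' @param sigma positive kernel width (default 1).
#' @return similarity value(s) in (0, 1].
#' @export
nca_kernel <- function(z, sigma = 1) {
  if (sigma <= 0) stop("sigma must be positive")
  if (any(z < 0)) stop("distances must be nonnegative")
  exp(-z / sigma)
}

# n x n weighted L1 distance matrix under squared weights
nca_dist_matrix <- function(X, w) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  w2 <- w^2
  for (r in which(w2 > 0)) {
    xr <- X[, r]
    D <- D + w2[r] * abs(outer(xr, xr, "-"))
  }
  D
}

# row-stochastic reference probabilities from a distance matrix
nca_probs_from_dist <- function(D, sigma) {
  n <- nrow(D)
  diag(D) <- Inf
  shift <- apply(D, 1, min)
  shift[!is.finite(shift)] <- 0
  E <- exp(-(D - shift) / sigma)   # row-wise shift cancels in normalization
  E[!is.finite(E)] <- 0
  diag(E) <- 0
  P <- E / rowSums(E)
  P
}

#' Leave-one-out reference probabilities
#'
#' Probability that sample j serves as the reference point for sample i:
#' p_ij proportional to the kernel similarity exp(-d_w(x_i, x_j) / sigma)
#' over all j != i; the diagonal is 0 and every row sums to 1.
#'
#' @param X numeric matrix, samples x features (n >= 2).
#' @param w feature weight vector.
#' @param sigma kernel width.
#' @return n x n matrix of reference probabilities.
#' @export
nca_reference_prob <- function(X, w, sigma = 1) {
  if (nrow(X) < 2) stop("need at least 2 samples")
  if (sigma <= 0) stop("sigma must be positive")
  nca_probs_from_dist(nca_dist_matrix(X, w), sigma)
}

#' Per-sample leave-one-out correct-classification probability
#'
#' p_i = sum over j != i of p_ij * 1[label_i == label_j]: the probability
#' that a stochastic same-class reference draw labels sample i correctly.
#'
#' @param P reference-probability matrix from [nca_reference_prob()].
#' @param y class labels, one per row of `P`.
#' @return numeric vector of probabilities in [0, 1].
#' @export
nca_loo_prob <- function(P, y) {
  y <- as.character(y)
  same <- outer(y, y, "==")
  rowSums(P * same)
}

#' Regularized NCA objective (maximized form)
#'
#' F(w) = (1/n) sum_i p_i - lambda * sum_r w_r^2: mean leave-one-out
#' correct-classification probability penalized by an L2 term on the weights.
#' The solver minimizes the equivalent loss 1 - F(w).
#'
#' @param X samples x features matrix.
#' @param y class labels.
#' @param w weight vector.
#' @param sigma kernel width.
#' @param lambda regularization strength (>= 0).
#' @return the objective value F(w).
#' @export
nca_objective <- function(X, y, w, sigma = 1, lambda = 0) {
  P <- nca_reference_prob(X, w, sigma)
  mean(nca_loo_prob(P, y)) - lambda * sum(w^2)
}

#' Analytic gradient of the NCA loss
#'
#' Gradient, with respect to each weight w_r, of the minimized loss
#' L(w) = (1/n) sum_{i, j != i} p_ij 1[label_i != label_j] + lambda sum w_r^2
#' (equal to 1 - F(w)). Used by the solver and validated against central
#' finite differences in the test suite.
#'
#' @inheritParams nca_objective
#' @return gradient vector, one entry per feature.
#' @export
nca_gradient <- function(X, y, w, sigma = 1, lambda = 0) {
  n <- nrow(X)
  P <- nca_reference_prob(X, w, sigma)
  mism <- outer(as.character(y), as.character(y), "!=")
  M <- P * mism
  s <- rowSums(M)
  C <- P * s - M                       # rows of P scaled by s_i, minus M
  g <- numeric(ncol(X))
  for (r in seq_len(ncol(X))) {
    xr <- X[, r]
    g[r] <- sum(C * abs(outer(xr, xr, "-")))
  }
  (2 * w / (n * sigma)) * g + 2 * lambda * w
}

nca_loss <- function(X, y, w, sigma, lambda, mism) {
  P <- nca_probs_from_dist(nca_dist_matrix(X, w), sigma)
  sum(P * mism) / nrow(X) + lambda * sum(w^2)
}

# n^2 x p stacked |x_ir - x_jr| matrix; lets the solver evaluate distances
# and gradients as single matrix products when memory allows
nca_absdiff <- function(X) {
  n <- nrow(X)
  A <- matrix(0, n * n, ncol(X))
  for (r in seq_len(ncol(X)))
    A[, r] <- abs(rep(X[, r], times = n) - rep(X[, r], each = n))
  A
}

nca_loss_fast <- function(A, n, w, sigma, lambda, mism) {
  D <- matrix(A %*% (w^2), n, n)
  P <- nca_probs_from_dist(D, sigma)
  list(loss = sum(P * mism) / n + lambda * sum(w^2), P = P)
}

nca_grad_fast <- function(A, n, P, mism, w, sigma, lambda) {
  M <- P * mism
  s <- rowSums(M)
  C <- P * s - M
  g <- as.vector(crossprod(A, as.vector(C)))
  (2 * w / (n * sigma)) * g + 2 * lambda * w
}

#' Fit NCA feature weights
#'
#' Learns one nonnegative-relevance weight per miRNA by minimizing the
#' regularized leave-one-out misclassification loss (1 - F(w)) with
#' deterministic gradient descent: all weights start at `init_weight`, steps
#' follow the analytic gradient with an Armijo backtracking line search, so
#' the recorded objective trace is non-increasing and refitting with the same
#' inputs reproduces identical weights.
#'
#' Features are transformed before fitting (default per-feature z-score over
#' the supplied samples) so that the kernel width sigma = 1 is comparable
#' across rpm scales; `transform = "identity"` disables this,
#' `"log2_zscore"` applies log2(rpm + 1) first.
#'
#' @param X samples x features matrix with column names.
#' @param y class labels (at least 2 classes).
#' @param sigma kernel width (default 1).
#' @param lambda L2 regularization; default `1 / nrow(X)`.
#' @param max_iter maximum gradient steps (default 100).
#' @param tol convergence tolerance on the loss decrease (default 1e-6).
#' @param init_weight starting value for every weight (default 1).
#' @param transform feature transform: `"zscore"` (default), `"identity"`, or
#'   `"log2_zscore"`.
#' @return object of class `nca`: weights `w` (named), `objective_trace`
#'   (loss per accepted iterate, non-increasing), `objective` (final F(w) on
#'   the transformed data), `converged`, `iterations`, and the fit
#'   configuration.
#' @seealso [nca_rank()] to turn a fit into a feature ranking.
#' @examples
#' set.seed(1)
#' X <- cbind(sig = c(rnorm(20, 0), rnorm(20, 3)), noise = rnorm(40))
#' fit <- nca(X, rep(c("a", "b"), each = 20), max_iter = 30)
#' coef(fit)
#' @export
nca <- function(X, y, sigma = 1, lambda = NULL, max_iter = 100, tol = 1e-6,
                init_weight = 1, transform = c("zscore", "identity", "log2_zscore")) {
  transform <- match.arg(transform)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- factor(y)
  if (nrow(X) < 2) stop("need at least 2 samples")
  if (nlevels(droplevels(y)) < 2) stop("need at least 2 classes")
  n <- nrow(X)
  if (is.null(lambda)) lambda <- 1 / n
  if (lambda < 0) stop("lambda must be nonnegative")
  if (sigma <= 0) stop("sigma must be positive")

  Xt <- if (transform == "log2_zscore") log2(X + 1) else X
  if (transform %in% c("zscore", "log2_zscore")) {
    ctr <- colMeans(Xt)
    scl <- apply(Xt, 2, stats::sd)
    scl[scl == 0] <- 1
    Xt <- scale(Xt, center = ctr, scale = scl)
  } else {
    ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  }

  mism <- outer(as.character(y), as.character(y), "!=")
  n_obs <- nrow(Xt)
  fast <- (as.double(n_obs)^2 * ncol(Xt)) <= 4e7
  A <- if (fast) nca_absdiff(Xt) else NULL
  eval_loss <- function(w) {
    if (fast) nca_loss_fast(A, n_obs, w, sigma, lambda, mism)
    else list(loss = nca_loss(Xt, y, w, sigma, lambda, mism), P = NULL)
  }
  eval_grad <- function(w, P) {
    if (fast) nca_grad_fast(A, n_obs, P, mism, w, sigma, lambda)
    else nca_gradient(Xt, y, w, sigma, lambda)
  }
  w <- rep(init_weight, ncol(X))
  cur <- eval_loss(w)
  loss <- cur$loss
  trace <- loss
  step <- 1
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    g <- eval_grad(w, cur$P)
    gn2 <- sum(g^2)
    if (sqrt(gn2) < 1e-10) { converged <- TRUE; break }
    accepted <- FALSE
    t <- step
    for (bt in 1:30) {
      w_new <- w - t * g
      new <- eval_loss(w_new)
      if (is.finite(new$loss) && new$loss <= loss - 1e-4 * t * gn2) {
        accepted <- TRUE
        break
      }
      t <- t / 2
    }
    if (!accepted) { converged <- TRUE; break }
    improved <- loss - new$loss
    w <- w_new
    cur <- new
    loss <- new$loss
    trace <- c(trace, loss)
    step <- t * 2                      # mild step growth for the next iterate
    if (improved < tol) { converged <- TRUE; break }
  }
  if (!is.finite(loss))
    stop("solver error: non-finite objective at iteration ", iter)
  names(w) <- colnames(X)
  structure(list(w = w,
                 objective_trace = trace,
                 objective = 1 - loss,
                 loss = loss,
                 converged = converged,
                 iterations = iter,
                 sigma = sigma, lambda = lambda,
                 transform = transform, center = ctr, scale = scl,
                 levels = levels(y),
                 call = match.call()),
            class = "nca")
}

#' @export
print.nca <- function(x, ...) {
  cat("NCA feature weighting: ", length(x$w), " features, ",
      x$iterations, " iterations (",
      if (x$converged) "converged" else "max_iter reached", ")\n", sep = "")
  cat("final loss ", format(x$loss, digits = 6),
      ", objective F(w) ", format(x$objective, digits = 6), "\n", sep = "")
  top <- sort(x$w^2, decreasing = TRUE)
  cat("largest squared weights:\n")
  print(utils::head(top, 5), digits = 4)
  invisible(x)
}

#' @export
coef.nca <- function(object, ...) object$w

#' @export
summary.nca <- function(object, ...) {
  out <- list(n_features = length(object$w),
              iterations = object$iterations,
              converged = object$converged,
              loss = object$loss,
              objective = object$objective,
              sigma = object$sigma, lambda = object$lambda,
              transform = object$transform,
              weight_sq = sort(object$w^2, decreasing = TRUE))
  class(out) <- "summary.nca"
  out
}

#' @export
print.summary.nca <- function(x, ...) {
  cat("NCA fit over", x$n_features, "features\n")
  cat("sigma =", x$sigma, " lambda =", format(x$lambda, digits = 4),
      " transform =", x$transform, "\n")
  cat("iterations:", x$iterations,
      if (x$converged) "(converged)" else "(max_iter)", "\n")
  cat("objective F(w):", format(x$objective, digits = 6), "\n")
  cat("squared-weight quartiles:\n")
  print(stats::quantile(x$weight_sq))
  invisible(x)
}

#' @export
plot.nca <- function(x, ...) {
  graphics::plot(x$w^2, type = "h", xlab = "feature index",
                 ylab = expression(w[r]^2),
                 main = "NCA squared feature weights", ...)
  invisible(x)
}

#' Rank features by NCA weight magnitude
#'
#' Orders features by descending squared weight (relevance magnitude); ties
#' break lexicographically by feature id. An all-zero weight vector yields a
#' purely lexicographic order flagged `degenerate`.
#'
#' @param fit an [nca()] fit.
#' @param k optional number of top features to keep (default all).
#' @return a `feature_ranking` data.frame with columns `mirna_id`, `score`
#'   (squared weight) and attribute `degenerate`.
#' @export
nca_rank <- function(fit, k = NULL) {
  stopifnot(inherits(fit, "nca"))
  if (!is.null(k) && k <= 0) stop("k must be positive")
  sq <- fit$w^2
  out <- data.frame(mirna_id = names(sq), score = unname(sq),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(k)) out <- utils::head(out, k)
  attr(out, "method") <- "NCA"
  attr(out, "degenerate") <- all(sq == 0)
  class(out) <- c("feature_ranking", "data.frame")
  out
}

#' Write feature weights as TSV
#' @param fit an [nca()] fit.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_nca_weights <- function(fit, path) {
  rk <- nca_rank(fit)
  out <- data.frame(mirna_id = names(fit$w),
                    weight = sprintf("%.10g", fit$w),
                    weight_squared_rank = match(names(fit$w), rk$mirna_id))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}
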