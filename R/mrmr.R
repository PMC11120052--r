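#' Plug-in mutual information of two discrete vectors
#'
#' Empirical estimate sum p(a,b) log p(a,b) / (p(a) p(b)) over the joint
#' contingency table, in bits by default. `mutual_information(x, x)` equals
#' the empirical entropy H(x).
#'
#' @param x,y discrete (integer/factor/character) vectors of equal length.
#' @param base `"bits"` (log2, default) or `"nats"` (natural log).
#' @return nonnegative mutual information estimate.
#' @export
mutual_information <- function(x, y, base = c("bits", "nats")) {
  base <- match.arg(base)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 observations")
  tab <- table(x, y)
  n <- sum(tab)
  pj <- tab / n
  px <- rowSums(pj)
  py <- colSums(pj)
  e <- outer(px, py)
  nz <- pj > 0
  mi <- sum(pj[nz] * log(pj[nz] / e[nz]))
  mi <- max(mi, 0)
  if (base == "bits") mi / log(2) else mi
}

#' Empirical entropy of a discrete vector
#' @param x discrete vector.
#' @inheritParams mutual_information
#' @return entropy H(x) >= 0.
#' @export
entropy <- function(x, base = c("bits", "nats")) {
  mutual_information(x, x, base = match.arg(base))
}

#' Relevance of a feature set to the stage labels
#'
#' Mean mutual information between each feature in the set and the class
#' label: V = (1/|S|) sum_{x in S} I(x, stage).
#'
#' @param Xd discretized feature matrix (samples x features, integer bins)
#'   with column names.
#' @param S character vector of feature ids (nonempty).
#' @param y class labels.
#' @inheritParams mutual_information
#' @return the relevance V.
#' @export
relevance <- function(Xd, S, y, base = c("bits", "nats")) {
  base <- match.arg(base)
  if (length(S) == 0) stop("feature set must be nonempty")
  mean(vapply(S, function(f) mutual_information(Xd[, f], y, base), numeric(1)))
}

#' Redundancy within a feature set
#'
#' Mean pairwise mutual information over all ordered pairs of the set,
#' including self-pairs, W = (1/|S|^2) sum_{x,z in S} I(x, z); the self-pair
#' I(x, x) = H(x) keeps W positive for any nonconstant set, which in turn
#' keeps the mutual-information quotient well defined. Set
#' `include_self = FALSE` to exclude the diagonal.
#'
#' @inheritParams relevance
#' @param include_self include self-pairs (default `TRUE`).
#' @return the redundancy W.
#' @export
redundancy <- function(Xd, S, base = c("bits", "nats"), include_self = TRUE) {
  base <- match.arg(base)
  m <- length(S)
  if (m == 0) stop("feature set must be nonempty")
  tot <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (!include_self && i == j) next
    tot <- tot + mutual_information(Xd[, S[i]], Xd[, S[j]], base)
  }
  tot / m^2
}

#' Mutual-information quotient of a candidate feature
#'
#' The greedy MRMR criterion: MIQ = V / W evaluated for the selected set plus
#' the candidate. With an empty selected set the quotient is taken over the
#' candidate alone, I(candidate, stage) / H(candidate). A zero redundancy
#' (possible only with `include_self = FALSE`) maps to `Inf` when V > 0 and 0
#' otherwise.
#'
#' @inheritParams redundancy
#' @param candidate feature id, not already in `S`.
#' @param y class labels.
#' @return the MIQ score.
#' @export
miq_score <- function(Xd, candidate, S, y, base = c("bits", "nats"),
                      include_self = TRUE) {
  base <- match.arg(base)
  if (candidate %in% S) stop("candidate already selected")
  Sc <- c(S, candidate)
  V <- relevance(Xd, Sc, y, base)
  W <- redundancy(Xd, Sc, base, include_self)
  if (W == 0) return(if (V > 0) Inf else 0)
  V / W
}

#' MRMR feature ranking by greedy forward addition
#'
#' Ranks features by repeatedly adding the candidate that maximizes the
#' mutual-information quotient MIQ = V / W of the augmented set, where V is
#' the mean feature-label mutual information (relevance) and W the mean
#' pairwise feature-feature mutual information (redundancy, self-pairs
#' included). Continuous features are first quantile-discretized with
#' [discretize()]; constant features are excluded up front with a message.
#' Ties break lexicographically by feature id, making the ranking
#' deterministic.
#'
#' @param X numeric matrix, samples x features, with column names.
#' @param y class labels (factor or vector).
#' @param k number of features to select (at most `ncol(X)`).
#' @param n_bins bins for discretization (default 4, equal frequency).
#' @inheritParams redundancy
#' @return object of class `mrmr_ranking`: data.frame with columns `mirna_id`
#'   (selection order), `score` (MIQ at selection), `relevance_V`,
#'   `redundancy_W`.
#' @export
mrmr <- function(X, y, k, n_bins = 4, base = c("bits", "nats"),
                 include_self = TRUE) {
  base <- match.arg(base)
  y <- factor(y)
  if (k > ncol(X)) stop("k exceeds the number of features (", ncol(X), ")")
  if (k <= 0) stop("k must be positive")
  Xd <- matrix(0L, nrow(X), ncol(X), dimnames = dimnames(X))
  uninf <- logical(ncol(X))
  for (j in seq_len(ncol(X))) {
    b <- discretize(X[, j], n_bins)
    uninf[j] <- attr(b, "uninformative")
    Xd[, j] <- b
  }
  if (any(uninf))
    message("excluding ", sum(uninf), " constant feature(s) before selection")
  feats <- colnames(X)[!uninf]
  if (k > length(feats))
    stop("k exceeds the number of usable (non-constant) features")
  logb <- if (base == "bits") log(2) else 1

  mi2 <- function(a, b) {          # plug-in MI on integer bin vectors
    tab <- table(a, b)
    pj <- tab / sum(tab)
    e <- outer(rowSums(pj), colSums(pj))
    nz <- pj > 0
    max(sum(pj[nz] * log(pj[nz] / e[nz])), 0) / logb
  }
  rel <- vapply(feats, function(f) mi2(Xd[, f], y), numeric(1))
  H <- vapply(feats, function(f) mi2(Xd[, f], Xd[, f]), numeric(1))

  sel <- character(0)
  miq_at <- V_at <- W_at <- numeric(0)
  V_sum <- 0          # sum of I(s, y) over selected
  W_pairsum <- 0      # sum of I(a, b) over all ordered selected pairs (incl self)
  cross <- stats::setNames(numeric(length(feats)), feats) # sum_{s in sel} I(cand, s)
  remaining <- feats
  for (step in seq_len(k)) {
    m <- length(sel) + 1L
    V <- (V_sum + rel[remaining]) / m
    selfH <- if (include_self) H[remaining] else 0
    W <- (W_pairsum + 2 * cross[remaining] + selfH) / m^2
    miq <- ifelse(W == 0, ifelse(V > 0, Inf, 0), V / W)
    best <- remaining[order(-miq, remaining)][1]
    sel <- c(sel, best)
    miq_at <- c(miq_at, miq[[match(best, remaining)]])
    V_at <- c(V_at, V[[match(best, remaining)]])
    W_at <- c(W_at, W[[match(best, remaining)]])
    V_sum <- V_sum + rel[[best]]
    W_pairsum <- W_pairsum + 2 * cross[[best]] +
      (if (include_self) H[[best]] else 0)
    remaining <- setdiff(remaining, best)
    if (length(remaining))
      cross[remaining] <- cross[remaining] +
        vapply(remaining, function(f) mi2(Xd[, f], Xd[, best]), numeric(1))
  }
  out <- data.frame(mirna_id = sel, score = miq_at,
                    relevance_V = V_at, redundancy_W = W_at,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- "MRMR"
  attr(out, "n_bins") <- n_bins
  attr(out, "base") <- base
  attr(out, "include_self") <- include_self
  class(out) <- c("mrmr_ranking", "feature_ranking", "data.frame")
  out
}
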