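# Independent oracles used to validate the implementation. These deliberately
# use naive/brute-force formulations and share no code with the package
# internals.

# Bernoulli log-likelihood as a per-row probability product (log scale).
naive_bernoulli_loglik <- function(X, y, theta, intercept) {
  eta <- as.vector(as.matrix(X) %*% theta) + intercept
  p <- 1 / (1 + exp(-eta))
  sum(log(ifelse(y == 1, p, 1 - p)))
}

# Unpenalized logistic MLE by Newton-Raphson (IRLS), written from the normal
# equations; independent of glm and glmnet.
newton_raphson_mle <- function(X, y, maxit = 200, tol = 1e-12) {
  X1 <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X1))
  for (i in seq_len(maxit)) {
    eta <- as.vector(X1 %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- p * (1 - p)
    score <- crossprod(X1, y - p)
    H <- crossprod(X1, w * X1)
    step <- solve(H, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  as.vector(beta)  # (intercept, coefficients)
}

# Brute-force knee: index maximizing the absolute discrete curvature (second
# difference) of the min-max normalized curve.
curvature_knee_oracle <- function(y) {
  yn <- (y - min(y)) / (max(y) - min(y))
  n <- length(yn)
  d2 <- abs(yn[3:n] - 2 * yn[2:(n - 1)] + yn[1:(n - 2)])
  which.max(d2) + 1L  # 1-based index of the interior point
}

# Random two-segment (steep then shallow) descending convex curve with a known
# break point. Returns the values and the 1-based break index.
random_two_segment_curve <- function(n = NULL) {
  if (is.null(n)) n <- sample(8:50, 1)
  brk <- sample(3:(n - 3), 1)
  s1 <- runif(1, 2, 10)
  s2 <- runif(1, 0.01, 0.2)
  vals <- c(s1 * (brk - 1):0, -s2 * seq_len(n - brk)) + s2 * (n - brk) + 1
  list(values = vals, break_index = brk, n = n)
}

# AUC as explicit pairwise concordance over all positive-negative pairs,
# counting ties as one half.
pairwise_auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  comp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(comp)
}
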