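test_that("the log-likelihood matches closed forms and the naive oracle", {
  # null model on n symmetric observations
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(c(0, 1), 10)
  expect_equal(logistic_loglik(X, y, c(0, 0), 0), 20 * log(0.5))
  # single observation at the decision boundary
  expect_equal(logistic_loglik(matrix(0, 1, 1), 1, 0, 0), log(0.5))
  # random instances against the per-row probability-product oracle
  set.seed(601)
  for (rep in 1:50) {
    n <- 50; p <- 3
    X <- matrix(rnorm(n * p), n, p)
    y <- rbinom(n, 1, 0.4)
    th <- rnorm(p); b <- rnorm(1)
    expect_equal(logistic_loglik(X, y, th, b),
                 naive_bernoulli_loglik(X, y, th, b), tolerance = 1e-12)
  }
  expect_error(logistic_loglik(matrix(Inf, 2, 1), c(0, 1), 1, 0), "non-finite")
})

test_that("total shrinkage drives the lasso to the intercept-only model", {
  dm <- tiny_design(n = 400, p = 5, seed = 11)
  m <- fit_penalized_logistic(dm$X, dm$y, "l1", 1e6 * nrow(dm$X))
  expect_true(all(m$theta == 0))
  expect_equal(m$intercept, qlogis(mean(dm$y)), tolerance = 1e-6)
})

test_that("the unpenalized fit agrees with the Newton-Raphson MLE", {
  dm <- tiny_design(n = 500, p = 5, seed = 12)
  m <- fit_penalized_logistic(dm$X, dm$y, "l1", 0)
  mle <- newton_raphson_mle(dm$X, dm$y)
  expect_lt(max(abs(m$theta - mle[-1])), 1e-4)
  expect_lt(abs(m$intercept - mle[1]), 1e-4)
  # same against base glm as a second, independent route
  gf <- glm.fit(cbind(1, dm$X), dm$y, family = binomial())
  expect_lt(max(abs(c(m$intercept, m$theta) - gf$coefficients)), 1e-4)
})

test_that("ridge coefficient norms shrink monotonically along the lambda path", {
  dm <- tiny_design(n = 400, p = 5, seed = 13)
  lams <- exp(seq(log(0.1), log(2000), length.out = 10))
  norms <- vapply(lams, function(l) {
    sqrt(sum(fit_penalized_logistic(dm$X, dm$y, "l2", l)$theta^2))
  }, 0)
  expect_true(all(diff(norms) <= 1e-8))
  expect_gt(norms[1], norms[10])
})

test_that("lasso sparsity is monotone in lambda and L2 keeps dense solutions", {
  sv <- small_survey(seed = 14, n = 2500, prevalence = 0.15)
  dm <- as_design_matrix(sv)
  g <- lambda_grid(dm$X, dm$y, "l1", 8)
  nnz <- vapply(g, function(l) {
    sum(fit_penalized_logistic(dm$X, dm$y, "l1", l, thresh = 1e-9)$theta != 0)
  }, 0)
  # g is decreasing, so support sizes must be nondecreasing, allowing
  # solver-tolerance ties at the zero threshold
  expect_true(all(diff(nnz) >= -1))
  expect_equal(nnz[1], 0)  # at lambda_max the solution is all-zero
  m2 <- fit_penalized_logistic(dm$X, dm$y, "l2", g[4])
  expect_gt(mean(m2$theta != 0), 0.9)
})

test_that("the stored objective equals its direct evaluation", {
  dm <- tiny_design(n = 300, p = 4, seed = 15)
  for (pen in c("l1", "l2")) {
    m <- fit_penalized_logistic(dm$X, dm$y, pen, 3)
    th_std <- m$theta * m$standardization$scale
    pen_val <- if (pen == "l1") sum(abs(th_std)) else sum(th_std^2)
    direct <- naive_bernoulli_loglik(dm$X, dm$y, m$theta, m$intercept) -
      3 * pen_val
    expect_equal(m$objective_value, direct, tolerance = 1e-8)
    # optimizer sanity: no worse than the null coefficient vector
    expect_gte(m$objective_value,
               naive_bernoulli_loglik(dm$X, dm$y, rep(0, 4), qlogis(mean(dm$y))))
  }
})

test_that("predicted probabilities are logistic, aligned by name, and guarded", {
  dm <- tiny_design(n = 50, p = 3, seed = 16)
  m <- fit_penalized_logistic(dm$X, dm$y, "l2", 1e6 * nrow(dm$X))
  m$theta[] <- 0; m$intercept <- 0
  expect_equal(unname(predict_proba(m, dm$X)), rep(0.5, 50))
  # hand-computed three-row example
  m$theta <- stats::setNames(c(1, -2, 0.5), colnames(dm$X))
  m$intercept <- 0.25
  X3 <- matrix(c(1, 0, 2, -1, 1, 0, 0.5, -0.5, 4), 3, 3, byrow = TRUE,
               dimnames = list(NULL, colnames(dm$X)))
  eta <- as.vector(X3 %*% m$theta) + 0.25
  expect_equal(unname(predict_proba(m, X3)), 1 / (1 + exp(-eta)))
  # overflow guard: extreme linear predictors stay inside (0, 1)
  Xbig <- matrix(c(1e4, -1e4, 1e4), 1, 3,
                 dimnames = list(NULL, colnames(dm$X)))
  p <- predict_proba(m, Xbig)
  expect_true(p > 0 && p < 1)
  # misaligned features fail loudly
  colnames(X3) <- c("a", "b", "c")
  expect_error(predict_proba(m, X3), "missing")
})

test_that("cross-validation folds honor the stratified contract", {
  set.seed(602)
  n <- 10000
  y <- as.numeric(seq_len(n) %in% sample(n, 150))  # 1.5% prevalence
  X <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  cv <- cross_validate_lambda(X, y, "l1", grid = c(5, 1), k = 5, seed = 3)
  f <- cv$fold_assignments
  expect_setequal(unique(f), 1:5)
  sizes <- tabulate(f, 5)
  expect_lte(diff(range(sizes)), 1)
  expect_equal(sum(sizes), n)
  for (k in 1:5) expect_setequal(unique(y[f == k]), c(0, 1))
  # selected lambda attains the grid maximum
  expect_equal(cv$lambda_star, cv$grid[which.max(cv$heldout_loglik)])
  # n divisible by k: all folds exactly equal
  cv2 <- cross_validate_lambda(X[1:1000, ], y[1:1000] * 0 + rep(c(0, 1), 500),
                               "l1", grid = c(5), k = 5, seed = 1)
  expect_equal(tabulate(cv2$fold_assignments, 5), rep(200L, 5))
  expect_equal(cv2$lambda_star, 5)
})

test_that("stratification failure with too few positives is reported", {
  y <- c(rep(0, 50), 1, 1)
  X <- matrix(rnorm(104), 52, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(cross_validate_lambda(X, y, "l1", grid = c(1), k = 5, seed = 1),
               "stratification failure")
})

test_that("CV-tuned lasso generalizes at least as well as the unpenalized fit", {
  # planted sparse truth: a handful of real effects among many noise dummies
  gen <- function(seed) {
    set.seed(seed)
    n <- 5000
    X <- matrix(rbinom(n * 41, 1, 0.3), n, 41,
                dimnames = list(NULL, paste0("d", 1:41)))
    eta <- X[, 1:5] %*% c(1.2, -1, 0.9, 0.8, -0.7) - 1.5
    list(X = X, y = rbinom(n, 1, 1 / (1 + exp(-eta))))
  }
  tr <- gen(603); te <- gen(604)
  fit <- penlogit_cv(tr$X, tr$y, "l1", k = 5, seed = 1)
  mle <- fit_penalized_logistic(tr$X, tr$y, "l1", 0)
  ll_cv <- logistic_loglik(te$X, te$y, fit$model$theta, fit$model$intercept)
  ll_mle <- logistic_loglik(te$X, te$y, mle$theta, mle$intercept)
  expect_gte(ll_cv, ll_mle)
})

test_that("models serialize to JSON and back without loss", {
  dm <- tiny_design(n = 200, p = 4, seed = 17)
  m <- fit_penalized_logistic(dm$X, dm$y, "l2", 2.5)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2$theta, m$theta)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$lambda, m$lambda)
  expect_equal(m2$penalty, m$penalty)
  expect_equal(m2$standardization$scale, m$standardization$scale)
  expect_equal(unname(predict_proba(m2, dm$X)), unname(predict_proba(m, dm$X)))
})
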