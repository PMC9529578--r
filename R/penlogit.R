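# Penalized logistic regression (lasso / ridge) with cross-validated tuning.
#
# The model maximizes, over standardized columns with an unpenalized intercept,
#
#   l(theta) = sum_i -log(1 + exp(-eta_i)) + sum_{y_i = 0} -eta_i  -  penalty
#
# with eta = X theta + b, penalty = lambda * |theta|_1 (lasso) or
# lambda * |theta|_2^2 (ridge).  The data term is the Bernoulli log-likelihood
# under the logistic link; lambda is on the total-log-likelihood scale.
# Optimization is delegated to glmnet, whose per-observation objective
# (1/n) loglik - lambda_g * [alpha |t|_1 + (1-alpha) |t|_2^2 / 2] maps to the
# scale above via lambda_g = lambda / n (L1) and lambda_g = 2 lambda / n (L2).

# Threshold below which a standardized coefficient counts as exactly zero.
ZERO_TOL <- 1e-8

#' Bernoulli log-likelihood under the logistic link
#'
#' Computes \eqn{\sum_i [y_i \eta_i - \log(1 + e^{\eta_i})]} with
#' \eqn{\eta = X\theta + b}, using an overflow-safe softplus. This equals the
#' form \eqn{\sum_i -\log(1+e^{-\eta_i}) + \sum_{y_i=0} -\eta_i} used to define
#' the penalized objectives.
#'
#' @param X numeric matrix (n x p), no missing values.
#' @param y binary 0/1 outcome vector of length n.
#' @param theta numeric coefficient vector of length p.
#' @param intercept scalar intercept.
#' @return The total log-likelihood (a scalar, always <= 0).
#' @export
logistic_loglik <- function(X, y, theta, intercept = 0) {
  X <- as.matrix(X)
  y <- check_binary(y)
  if (ncol(X) != length(theta))
    stop("length(theta) must equal ncol(X)", call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(theta)) || !is.finite(intercept))
    stop("non-finite values in X, theta or intercept", call. = FALSE)
  eta <- as.vector(X %*% theta) + intercept
  sum(y * eta - softplus(eta))
}

# glmnet-style standardization constants: mean and population (1/n) sd.
standardization_constants <- function(X) {
  n <- nrow(X)
  center <- colMeans(X)
  scale <- sqrt(colMeans(X^2) - center^2)
  scale[scale < .Machine$double.eps] <- 0
  list(center = center, scale = scale)
}

lambda_to_glmnet <- function(lambda, n, penalty) {
  switch(penalty, l1 = lambda / n, l2 = 2 * lambda / n)
}

# one-hot design matrices are mostly zeros; glmnet is markedly faster on a
# sparse representation
maybe_sparse <- function(X) {
  if (is.matrix(X) && mean(X == 0) > 0.4) Matrix::Matrix(X, sparse = TRUE)
  else X
}

#' Construct a default lambda grid
#'
#' Fifty log-spaced penalty values descending from \eqn{\lambda_{max}} (the
#' smallest lambda at which the lasso solution is all-zero, computed as
#' \eqn{\max_j |x_j^\top (y - \bar y)|} over standardized columns). The lasso
#' grid descends two decades: at the sample sizes and feature counts this
#' pipeline targets, the cross-validated optimum sits well inside that span,
#' and the nearly-unpenalized fits below it cost most of the path time while
#' never being selected. The ridge, which no finite lambda annihilates, spans
#' \eqn{100\,\lambda_{max}} down four decades.
#'
#' @param X feature matrix.
#' @param y binary outcome.
#' @param penalty `"l1"` or `"l2"`.
#' @param n_lambda number of grid points (default 50).
#' @param ratio ratio of smallest to largest lambda; defaults to 1e-2 for the
#'   lasso and 1e-4 for the ridge.
#' @return Decreasing numeric vector of lambda values (total-loglik scale).
#' @export
lambda_grid <- function(X, y, penalty = c("l1", "l2"), n_lambda = 50,
                        ratio = NULL) {
  penalty <- match.arg(penalty)
  if (is.null(ratio)) ratio <- switch(penalty, l1 = 1e-2, l2 = 1e-4)
  X <- as.matrix(X)
  y <- check_binary(y)
  sc <- standardization_constants(X)
  ok <- sc$scale > 0
  r <- y - mean(y)
  lmax <- if (any(ok)) {
    max(abs(crossprod(sweep(sweep(X[, ok, drop = FALSE], 2, sc$center[ok]),
                            2, sc$scale[ok], "/"), r)))
  } else 1
  lmax <- max(lmax, .Machine$double.eps)
  if (penalty == "l2") lmax <- lmax * 100
  exp(seq(log(lmax), log(lmax * ratio), length.out = n_lambda))
}

#' Fit a penalized logistic regression at a fixed lambda
#'
#' Maximizes the penalized Bernoulli log-likelihood
#' \eqn{l(\theta) - \lambda\|\theta\|_1} (lasso) or
#' \eqn{l(\theta) - \lambda\|\theta\|_2^2} (ridge) over standardized columns,
#' with an unpenalized intercept. Returned coefficients are back-transformed to
#' the raw column scale. At `lambda = 0` the fit is the ordinary maximum
#' likelihood estimate.
#'
#' @param X numeric feature matrix with column names.
#' @param y binary 0/1 outcome; both classes must be present.
#' @param penalty `"l1"` (lasso) or `"l2"` (ridge).
#' @param lambda nonnegative penalty strength on the total-log-likelihood
#'   scale.
#' @param thresh glmnet convergence threshold.
#' @return A `penlogit` object: named coefficients `theta` (raw scale),
#'   `intercept`, `lambda`, `penalty`, `converged`, `objective_value` (the
#'   penalized log-likelihood at the optimum, with the penalty applied to the
#'   standardized-scale coefficients), and the `standardization` constants.
#' @export
fit_penalized_logistic <- function(X, y, penalty = c("l1", "l2"), lambda,
                                   thresh = 1e-10) {
  penalty <- match.arg(penalty)
  X <- as.matrix(X)
  y <- check_binary(y)
  stopifnot(length(lambda) == 1L, lambda >= 0)
  if (length(unique(y)) < 2L)
    stop("y must contain both classes", call. = FALSE)
  if (!all(is.finite(X))) stop("X contains non-finite values", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))

  n <- nrow(X)
  sc <- standardization_constants(X)
  alpha <- if (penalty == "l1") 1 else 0
  lam_g <- lambda_to_glmnet(lambda, n, penalty)

  # glmnet is most accurate when the target lambda terminates a decreasing
  # path (warm starts); build one down from above lambda_max.
  sc_ok <- sc$scale > 0
  lam_top <- {
    r <- y - mean(y)
    Z <- sweep(sweep(X[, sc_ok, drop = FALSE], 2, sc$center[sc_ok]),
               2, sc$scale[sc_ok], "/")
    top <- if (any(sc_ok)) max(abs(crossprod(Z, r))) / n else 1
    max(top, lam_g, .Machine$double.eps) * 1.05
  }
  path <- if (lam_g > 0) {
    if (lam_top / lam_g < 1.01) lam_g * c(1.02, 1)
    else exp(seq(log(lam_top), log(lam_g), length.out = 25))
  } else {
    c(exp(seq(log(lam_top), log(lam_top * 1e-8), length.out = 30)), 0)
  }

  fit <- glmnet::glmnet(maybe_sparse(X), y, family = "binomial",
                        alpha = alpha, lambda = path, standardize = TRUE,
                        thresh = thresh, maxit = 1e6)
  k <- length(fit$lambda)  # glmnet may truncate the path; take the last fit
  theta <- as.numeric(fit$beta[, k])
  b0 <- as.numeric(fit$a0[k])
  names(theta) <- rownames(fit$beta)

  theta_std <- theta * sc$scale
  theta[abs(theta_std) < ZERO_TOL] <- 0
  theta_std <- theta * sc$scale

  converged <- TRUE
  if (lambda == 0 && max(abs(theta_std), 0) > 25) {
    converged <- FALSE
    warning("unpenalized fit did not converge (possible separation)",
            call. = FALSE)
  }
  if (abs(fit$lambda[k] - lam_g) > 1e-6 * max(lam_g, 1)) {
    converged <- FALSE
    warning("solver stopped before reaching the requested lambda",
            call. = FALSE)
  }

  pen <- switch(penalty, l1 = sum(abs(theta_std)), l2 = sum(theta_std^2))
  obj <- logistic_loglik(X, y, theta, b0) - lambda * pen

  structure(list(
    penalty = penalty, lambda = lambda, theta = theta, intercept = b0,
    converged = converged, objective_value = obj,
    standardization = sc, feature_names = names(theta), n = n
  ), class = "penlogit")
}

#' @export
coef.penlogit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$theta)
}

#' @export
print.penlogit <- function(x, ...) {
  nz <- sum(x$theta != 0)
  cat(sprintf(
    "Penalized logistic regression (%s), lambda = %.4g\n  %d features, %d nonzero; intercept = %.4f; objective = %.4f%s\n",
    toupper(x$penalty), x$lambda, length(x$theta), nz, x$intercept,
    x$objective_value, if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Names of features with nonzero coefficients
#' @param model a `penlogit` fit.
#' @return Character vector of feature names with nonzero coefficients.
#' @export
nonzero_features <- function(model) {
  stopifnot(inherits(model, "penlogit"))
  model$feature_names[model$theta != 0]
}

#' Predicted outcome probabilities
#'
#' Aligns `X` to the model's features by column name and returns
#' \eqn{1/(1+e^{-\eta})}, clipped into the open interval (0, 1).
#'
#' @param model a `penlogit` fit.
#' @param X matrix (or `design_matrix`) containing at least the model's
#'   feature columns, matched by name.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "penlogit"))
  if (inherits(X, "design_matrix")) X <- X$X
  X <- as.matrix(X)
  miss <- setdiff(model$feature_names, colnames(X))
  if (length(miss))
    stop("features missing from X: ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  eta <- as.vector(X[, model$feature_names, drop = FALSE] %*% model$theta) +
    model$intercept
  sigmoid(eta)
}

#' @export
predict.penlogit <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "design_matrix")) newdata <- newdata$X
  if (type == "response") return(predict_proba(object, newdata))
  as.vector(as.matrix(newdata)[, object$feature_names, drop = FALSE] %*%
              object$theta) + object$intercept
}

# Stratified fold assignment: preserves outcome prevalence per fold and keeps
# overall fold sizes within one of each other.
stratified_folds <- function(y, k, seed) {
  n <- length(y)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  pos <- which(y == 1); neg <- which(y == 0)
  if (length(pos) < k || length(neg) < k)
    stop(sprintf(
      "stratification failure: need at least %d observations of each class, have %d positives / %d negatives",
      k, length(pos), length(neg)), call. = FALSE)
  fold <- integer(n)
  with_seed(derive_seed(seed, "folds"), {
    # overall fold sizes within 1; extra records land in random folds
    target <- rep(n %/% k, k)
    extra <- sample(k, n %% k)
    target[extra] <- target[extra] + 1
    # positives spread as evenly as possible, their remainder going to the
    # larger folds so that the negative counts stay nonnegative
    pcount <- rep(length(pos) %/% k, k)
    rp <- length(pos) %% k
    if (rp > 0) {
      big <- order(-target)[seq_len(rp)]
      pcount[big] <- pcount[big] + 1
    }
    qcount <- target - pcount
    if (any(qcount < 0)) {  # degenerate class balance: cyclic fallback
      fold[sample(pos)] <- rep_len(seq_len(k), length(pos))
      fold[sample(neg)] <- rep_len(seq_len(k), length(neg))
    } else {
      fold[sample(pos)] <- rep(seq_len(k), times = pcount)
      fold[sample(neg)] <- rep(seq_len(k), times = qcount)
    }
  })
  fold
}

#' Cross-validate the penalty strength
#'
#' k-fold cross-validation for lambda: for each candidate, the model is fit on
#' k-1 folds and the Bernoulli log-likelihood is evaluated on the held-out
#' fold; the lambda maximizing the mean held-out log-likelihood is selected.
#' Folds are stratified on the outcome (each fold keeps both classes, which at
#' 1-2% prevalence unstratified folds can lose) and fold sizes differ by at
#' most one. Ties on the criterion resolve to the largest (most parsimonious)
#' lambda.
#'
#' @param X feature matrix.
#' @param y binary outcome.
#' @param penalty `"l1"` or `"l2"`.
#' @param grid decreasing vector of candidate lambdas; default [lambda_grid()].
#' @param k number of folds (default 5).
#' @param seed integer seed controlling fold assignment.
#' @return A `cv_penlogit` object: `grid`, `fold_assignments`,
#'   `heldout_loglik` (mean held-out log-likelihood per lambda) and
#'   `lambda_star`.
#' @export
cross_validate_lambda <- function(X, y, penalty = c("l1", "l2"), grid = NULL,
                                  k = 5, seed = 1, thresh = 1e-6) {
  penalty <- match.arg(penalty)
  X <- as.matrix(X)
  y <- check_binary(y)
  if (is.null(grid)) grid <- lambda_grid(X, y, penalty)
  stopifnot(length(grid) >= 1, !is.unsorted(rev(grid)))
  fold <- stratified_folds(y, k, seed)
  alpha <- if (penalty == "l1") 1 else 0

  Xsp <- maybe_sparse(X)
  ll <- matrix(NA_real_, nrow = k, ncol = length(grid))
  for (f in seq_len(k)) {
    tr <- fold != f
    lam_g <- lambda_to_glmnet(grid, sum(tr), penalty)
    fit <- glmnet::glmnet(Xsp[tr, , drop = FALSE], y[tr], family = "binomial",
                          alpha = alpha, lambda = lam_g, standardize = TRUE,
                          thresh = thresh, maxit = 1e6)
    eta <- predict(fit, Xsp[!tr, , drop = FALSE], s = lam_g, type = "link",
                   exact = FALSE)
    yh <- y[!tr]
    ll[f, ] <- colSums(yh * eta - softplus(eta))
  }
  heldout <- colMeans(ll)
  structure(list(
    grid = grid, fold_assignments = fold, heldout_loglik = heldout,
    lambda_star = grid[which.max(heldout)], k = k, penalty = penalty
  ), class = "cv_penlogit")
}

#' @export
print.cv_penlogit <- function(x, ...) {
  cat(sprintf(
    "%d-fold CV over %d lambdas (%s): lambda* = %.4g (held-out loglik %.2f)\n",
    x$k, length(x$grid), toupper(x$penalty), x$lambda_star,
    max(x$heldout_loglik)))
  invisible(x)
}

#' Cross-validated penalized logistic fit
#'
#' Convenience wrapper: [cross_validate_lambda()] followed by
#' [fit_penalized_logistic()] at the selected lambda on the full data.
#'
#' @inheritParams cross_validate_lambda
#' @param refit_thresh glmnet threshold for the final refit at the selected
#'   lambda.
#' @return List with elements `model` (a `penlogit`) and `cv`
#'   (a `cv_penlogit`).
#' @export
penlogit_cv <- function(X, y, penalty = c("l1", "l2"), grid = NULL, k = 5,
                        seed = 1, thresh = 1e-6, refit_thresh = 1e-8) {
  penalty <- match.arg(penalty)
  cv <- cross_validate_lambda(X, y, penalty, grid = grid, k = k, seed = seed,
                              thresh = thresh)
  model <- fit_penalized_logistic(X, y, penalty, cv$lambda_star,
                                  thresh = refit_thresh)
  list(model = model, cv = cv)
}

#' Serialize / restore a fitted model as JSON
#'
#' @param model a `penlogit` fit.
#' @param path file path to write to / read from.
#' @return `write_model` invisibly returns `path`; `read_model` returns the
#'   restored `penlogit` object.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "penlogit"))
  obj <- list(
    penalty = model$penalty, lambda = model$lambda,
    intercept = model$intercept,
    theta = as.list(model$theta),
    converged = model$converged, objective_value = model$objective_value,
    standardization = list(center = as.list(model$standardization$center),
                           scale = as.list(model$standardization$scale)),
    n = model$n)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path)
  theta <- unlist(obj$theta)
  structure(list(
    penalty = obj$penalty, lambda = obj$lambda, theta = theta,
    intercept = obj$intercept, converged = obj$converged,
    objective_value = obj$objective_value,
    standardization = list(center = unlist(obj$standardization$center),
                           scale = unlist(obj$standardization$scale)),
    feature_names = names(theta), n = obj$n
  ), class = "penlogit")
}
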