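# Feed-forward neural-network validator.
#
# A fully connected net (default four hidden layers, tapering widths, ReLU,
# sigmoid output) is trained by mini-batch Adam on the lasso-selected
# features, with early stopping on a stratified validation split. Per-feature
# importance is measured by permutation (mean held-out AUC drop over R
# permutations) or by first-layer weight magnitude, then knee-selected with
# the same detector used for the ridge coefficients and compared against the
# ITA selection.

#' Neural network configuration
#'
#' @param hidden_layers number of hidden layers (default 4).
#' @param hidden_widths units per hidden layer; must have length
#'   `hidden_layers`. The default tapering pyramid 64-32-16-8 keeps capacity
#'   modest for tabular dummy inputs.
#' @param activation hidden activation (`"relu"`).
#' @param epochs maximum training epochs.
#' @param batch_size mini-batch size.
#' @param learning_rate Adam step size.
#' @param val_fraction fraction of the training data held out (stratified) for
#'   early stopping; 0 disables early stopping.
#' @param patience epochs without validation improvement before stopping.
#' @param seed integer seed; training is deterministic given it.
#' @return An `nn_config` list.
#' @export
nn_config <- function(hidden_layers = 4,
                      hidden_widths = c(64, 32, 16, 8),
                      activation = "relu",
                      epochs = 50, batch_size = 256, learning_rate = 1e-3,
                      val_fraction = 0.1, patience = 5, seed = 1) {
  stopifnot(hidden_layers >= 1, length(hidden_widths) == hidden_layers,
            all(hidden_widths >= 1), epochs >= 0, batch_size >= 1,
            learning_rate > 0, val_fraction >= 0, val_fraction < 1)
  activation <- match.arg(activation, "relu")
  structure(as.list(environment()), class = "nn_config")
}

relu <- function(x) x * (x > 0)

nn_forward <- function(W, b, X) {
  a <- X
  acts <- list(a)
  L <- length(W)
  for (l in seq_len(L - 1)) {
    a <- relu(sweep(a %*% W[[l]], 2, b[[l]], "+"))
    acts[[l + 1]] <- a
  }
  z <- as.vector(a %*% W[[L]]) + b[[L]]
  list(p = sigmoid(z), acts = acts)
}

#' Train a feed-forward network on lasso-selected features
#'
#' @param train a `design_matrix` (or list with `X`, `y`) whose columns are
#'   the model inputs — typically the design matrix restricted to the lasso
#'   support.
#' @param config an [nn_config()].
#' @param features optional character vector restricting `train$X` columns
#'   (e.g. the lasso support).
#' @return An `ita_nn` object with layer weights, standardization constants,
#'   training history and the epoch of the restored (best-validation) weights.
#' @export
fit_feedforward <- function(train, config = nn_config(), features = NULL) {
  stopifnot(inherits(config, "nn_config"))
  X <- as.matrix(if (inherits(train, "design_matrix") || is.list(train))
    train$X else train)
  y <- check_binary(train$y)
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  if (length(unique(y)) < 2) stop("y must contain both classes", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))

  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale < .Machine$double.eps] <- 1
  Z <- sweep(sweep(X, 2, center), 2, scale, "/")

  widths <- c(p, config$hidden_widths, 1)
  L <- length(widths) - 1

  result <- with_seed(derive_seed(config$seed, "nn-train"), {
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {  # He-normal initialization
      W[[l]] <- matrix(stats::rnorm(widths[l] * widths[l + 1],
                                    sd = sqrt(2 / widths[l])),
                       widths[l], widths[l + 1])
      b[[l]] <- rep(0, widths[l + 1])
    }
    b[[L]] <- stats::qlogis(mean(y))  # start at the base rate

    # stratified validation split for early stopping
    val_idx <- integer(0)
    if (config$val_fraction > 0 && config$epochs > 0) {
      pos <- which(y == 1); neg <- which(y == 0)
      nv_pos <- max(1L, round(config$val_fraction * length(pos)))
      nv_neg <- max(1L, round(config$val_fraction * length(neg)))
      if (length(pos) > nv_pos && length(neg) > nv_neg)
        val_idx <- c(sample(pos, nv_pos), sample(neg, nv_neg))
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    Ztr <- Z[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]

    bce <- function(p, yy) -mean(yy * log(p) + (1 - yy) * log(1 - p))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t <- 0
    best <- list(W = W, b = b, loss = Inf, epoch = 0L)
    history <- numeric(0); wait <- 0L

    for (epoch in seq_len(config$epochs)) {
      ord <- sample(length(ytr))
      starts <- seq(1, length(ytr), by = config$batch_size)
      for (s in starts) {
        ii <- ord[s:min(s + config$batch_size - 1, length(ytr))]
        Xb <- Ztr[ii, , drop = FALSE]; yb <- ytr[ii]
        fw <- nn_forward(W, b, Xb)
        # backprop: delta at the output on the logit scale
        delta <- matrix((fw$p - yb) / length(yb), ncol = 1)
        t <- t + 1
        for (l in L:1) {
          gW <- crossprod(fw$acts[[l]], delta)
          gb <- colSums(delta)
          if (l > 1)
            delta <- (delta %*% t(W[[l]])) * (fw$acts[[l]] > 0)
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          corr <- sqrt(1 - beta2^t) / (1 - beta1^t)
          W[[l]] <- W[[l]] - config$learning_rate * corr * mW[[l]] /
            (sqrt(vW[[l]]) + eps)
          b[[l]] <- b[[l]] - config$learning_rate * corr * mb[[l]] /
            (sqrt(vb[[l]]) + eps)
        }
      }
      mon_idx <- if (length(val_idx)) val_idx else tr_idx
      loss <- bce(nn_forward(W, b, Z[mon_idx, , drop = FALSE])$p, y[mon_idx])
      if (!is.finite(loss))
        stop("training failure: divergent loss at epoch ", epoch, call. = FALSE)
      history <- c(history, loss)
      if (loss < best$loss - 1e-6) {
        best <- list(W = W, b = b, loss = loss, epoch = epoch)
        wait <- 0L
      } else if (length(val_idx)) {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    if (config$epochs == 0 || best$epoch == 0L)
      best <- list(W = W, b = b, loss = NA_real_, epoch = 0L)
    list(W = best$W, b = best$b, history = history, best_epoch = best$epoch)
  })

  structure(list(
    W = result$W, b = result$b, center = center, scale = scale,
    feature_names = colnames(X), config = config,
    history = result$history, best_epoch = result$best_epoch
  ), class = "ita_nn")
}

#' @export
predict.ita_nn <- function(object, newdata, ...) {
  X <- as.matrix(if (is.list(newdata)) newdata$X else newdata)
  miss <- setdiff(object$feature_names, colnames(X))
  if (length(miss))
    stop("features missing from newdata: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  Z <- sweep(sweep(X[, object$feature_names, drop = FALSE], 2, object$center),
             2, object$scale, "/")
  nn_forward(object$W, object$b, Z)$p
}

#' @export
print.ita_nn <- function(x, ...) {
  cat(sprintf(
    "Feed-forward network: %d inputs -> %s -> 1 (sigmoid); best epoch %d of %d trained\n",
    length(x$feature_names),
    paste(x$config$hidden_widths, collapse = "-"), x$best_epoch,
    length(x$history)))
  invisible(x)
}

#' Per-feature importance of a fitted network
#'
#' Default method: permutation importance — the mean drop in held-out AUC over
#' `R` seeded permutations of each feature column, clipped at zero for
#' ranking. `"weight"` scores each input by the L1 norm of its first-layer
#' weights. The result is a `coef_curve` (sorted descending, knee located), so
#' knee selection works exactly as for ridge coefficients; unclipped scores
#' and their Monte-Carlo standard errors are attached.
#'
#' @param network an `ita_nn` fit.
#' @param data held-out `design_matrix` (or list with `X`, `y`).
#' @param method `"permutation"` or `"weight"`.
#' @param R permutations per feature.
#' @param seed integer seed for the permutations.
#' @param sensitivity Kneedle sensitivity for the knee on the importance
#'   curve.
#' @return A `coef_curve` with extra fields `raw` (named unclipped mean AUC
#'   drops), `se` (their standard errors), `baseline_auc` and `method`.
#' @export
nn_importance <- function(network, data, method = c("permutation", "weight"),
                          R = 20, seed = 1, sensitivity = 1) {
  method <- match.arg(method)
  stopifnot(inherits(network, "ita_nn"))
  feats <- network$feature_names
  if (method == "weight") {
    raw <- stats::setNames(rowSums(abs(network$W[[1]])), feats)
    se <- stats::setNames(rep(NA_real_, length(feats)), feats)
    base <- NA_real_
  } else {
    X <- as.matrix(if (is.list(data)) data$X else data)
    y <- check_binary(data$y)
    if (length(unique(y)) < 2 || nrow(X) < 10)
      stop("degenerate held-out set for permutation importance", call. = FALSE)
    X <- X[, feats, drop = FALSE]
    Z <- sweep(sweep(X, 2, network$center), 2, network$scale, "/")
    base <- auc_score(nn_forward(network$W, network$b, Z)$p, y)
    drops <- with_seed(derive_seed(seed, "nn-perm"), {
      vapply(seq_along(feats), function(j) {
        vapply(seq_len(R), function(r) {
          Zp <- Z
          Zp[, j] <- Z[sample(nrow(Z)), j]
          base - auc_score(nn_forward(network$W, network$b, Zp)$p, y)
        }, 0)
      }, numeric(R))
    })
    raw <- stats::setNames(colMeans(drops), feats)
    se <- stats::setNames(apply(drops, 2, stats::sd) / sqrt(R), feats)
  }
  curve <- new_coef_curve(unname(pmax(raw, 0)), feats, "absolute")
  if (length(feats) >= 4) {
    curve <- find_knee(curve, sensitivity)
  } else {
    curve$knee_index <- NA_integer_  # too few features to locate a bend
  }
  curve$raw <- raw
  curve$se <- se
  curve$baseline_auc <- base
  curve$method <- method
  curve
}

#' Compare two selected-feature sets
#'
#' @param ita_selected,nn_selected nonempty character vectors of selected
#'   feature names.
#' @return List with `intersection`, `jaccard`, `only_ita`, `only_nn` and the
#'   set sizes.
#' @export
compare_selections <- function(ita_selected, nn_selected) {
  if (length(ita_selected) == 0 || length(nn_selected) == 0)
    stop("both selections must be nonempty", call. = FALSE)
  inter <- intersect(ita_selected, nn_selected)
  uni <- union(ita_selected, nn_selected)
  list(intersection = inter,
       jaccard = length(inter) / length(uni),
       only_ita = setdiff(ita_selected, nn_selected),
       only_nn = setdiff(nn_selected, ita_selected),
       n_ita = length(unique(ita_selected)),
       n_nn = length(unique(nn_selected)))
}
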