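# Model evaluation: single stratified train/test split, ROC-AUC, balanced
# error rate. AUC is the probability that a random positive case outscores a
# random negative case (ties counted one half), computed via mid-ranks; this
# equals trapezoidal integration of the ROC curve.

#' Split a design matrix into training and test sets
#'
#' Draws a single random split (default 80/20). In stratified mode (default)
#' the split is drawn within each outcome class, preserving prevalence to
#' within one record per class — at 1-2% outcome prevalence an unstratified
#' split can leave one side without positives.
#'
#' @param dm a `design_matrix` (see [one_hot()]), or any list with elements
#'   `X` (matrix) and `y` (binary vector).
#' @param train_fraction fraction of records assigned to training, in (0,1).
#' @param seed integer seed; the same seed always yields the same assignment.
#' @param stratified draw the split within outcome classes (default TRUE).
#' @return List with `train` and `test` (each a subset with `X`, `y` and any
#'   other fields carried over) and the index vectors `train_idx`, `test_idx`.
#' @export
train_test_split <- function(dm, train_fraction = 0.8, seed = 1,
                             stratified = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  y <- check_binary(dm$y)
  n <- length(y)
  idx <- with_seed(derive_seed(seed, "split"), {
    if (stratified) {
      pos <- which(y == 1); neg <- which(y == 0)
      c(sample(pos, round(train_fraction * length(pos))),
        sample(neg, round(train_fraction * length(neg))))
    } else {
      sample(n, round(train_fraction * n))
    }
  })
  train_idx <- sort(idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  if (!stratified &&
      (length(unique(y[train_idx])) < 2 || length(unique(y[test_idx])) < 2))
    warning("a split side contains a single class; consider stratified = TRUE",
            call. = FALSE)
  subset_dm <- function(i) {
    out <- dm
    out$X <- dm$X[i, , drop = FALSE]
    out$y <- y[i]
    out
  }
  list(train = subset_dm(train_idx), test = subset_dm(test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the fraction of (positive, negative) pairs in which the
#' positive case receives the higher score, counting ties as one half.
#' Computed with mid-ranks, which is exact and equals trapezoidal integration
#' of the ROC curve.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- check_binary(labels, "labels")
  if (anyNA(scores)) stop("scores contain NA", call. = FALSE)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: labels contain a single class", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Balanced error rate
#'
#' The arithmetic mean of the per-class misclassification rates:
#' \eqn{BER = (FN/(TP+FN) + FP/(TN+FP)) / 2}. Insensitive to class imbalance,
#' which makes it informative for rare outcomes where raw accuracy is not.
#'
#' @param confusion named numeric vector or list with entries `tp`, `fp`,
#'   `tn`, `fn`.
#' @return BER in \[0, 1\].
#' @export
ber <- function(confusion) {
  cm <- as.list(confusion)
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  if (any(vapply(list(tp, fp, tn, fn), is.null, logical(1))))
    stop("confusion must provide tp, fp, tn, fn", call. = FALSE)
  if (tp + fn == 0 || tn + fp == 0)
    stop("BER undefined: a class has no test members", call. = FALSE)
  (fn / (tp + fn) + fp / (tn + fp)) / 2
}

confusion_counts <- function(scores, labels, threshold) {
  pred <- as.numeric(scores >= threshold)
  c(tp = sum(pred == 1 & labels == 1), fp = sum(pred == 1 & labels == 0),
    tn = sum(pred == 0 & labels == 0), fn = sum(pred == 0 & labels == 1))
}

#' Choose a decision threshold maximizing balanced accuracy
#'
#' Sweeps the ROC curve of the supplied (typically training) scores and
#' returns the threshold maximizing balanced accuracy, i.e. minimizing BER. A
#' probability cut of 0.5 on an unweighted fit at 1-2% prevalence classifies
#' every record negative (BER 0.5, uninformative), so the operating point is
#' chosen on the training data instead.
#'
#' @param scores numeric scores (e.g. predicted probabilities) on training
#'   data.
#' @param labels binary training labels.
#' @return A threshold value; predicting positive for `score >= threshold`
#'   maximizes balanced accuracy on the supplied data.
#' @export
choose_threshold <- function(scores, labels) {
  labels <- check_binary(labels, "labels")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("threshold undefined: labels contain a single class", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # candidate cuts after each distinct score value
  tpr <- cumsum(l == 1) / n1
  fpr <- cumsum(l == 0) / n0
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each distinct score
  bal <- (tpr[last] + 1 - fpr[last]) / 2
  s[last][which.max(bal)]
}

#' Evaluate predictions on a test set
#'
#' Computes AUC on the score scale and BER at a decision threshold. The
#' threshold defaults to the balanced-accuracy maximizer on the training data
#' (`threshold_mode = "balanced"`, requires `train`); `"fixed"` uses
#' `threshold` as given (default 0.5).
#'
#' @param model_or_scores a `penlogit` fit, an `ita_nn` network, or a numeric
#'   score vector aligned with `test$y`.
#' @param test a `design_matrix` (or list with `X`, `y`).
#' @param train optional training `design_matrix` used to tune the threshold.
#' @param threshold_mode `"balanced"` or `"fixed"`.
#' @param threshold the fixed threshold when `threshold_mode = "fixed"`.
#' @return An `eval_report`: `auc`, `ber`, `confusion` (tp/fp/tn/fn),
#'   `threshold`, `n_train`, `n_test`.
#' @export
evaluate <- function(model_or_scores, test, train = NULL,
                     threshold_mode = c("balanced", "fixed"), threshold = 0.5) {
  threshold_mode <- match.arg(threshold_mode)
  score_of <- function(d) {
    if (is.numeric(model_or_scores)) model_or_scores
    else if (inherits(model_or_scores, "penlogit")) predict_proba(model_or_scores, d)
    else if (inherits(model_or_scores, "ita_nn")) predict(model_or_scores, d)
    else stop("unsupported model type", call. = FALSE)
  }
  y_test <- check_binary(test$y)
  scores <- score_of(test)
  stopifnot(length(scores) == length(y_test))
  if (threshold_mode == "balanced") {
    if (is.null(train))
      stop("threshold_mode = \"balanced\" requires `train`", call. = FALSE)
    if (is.numeric(model_or_scores))
      stop("balanced threshold from raw scores requires a model; pass threshold_mode = \"fixed\"",
           call. = FALSE)
    threshold <- choose_threshold(score_of(train), check_binary(train$y))
  }
  cm <- confusion_counts(scores, y_test, threshold)
  structure(list(
    auc = auc_score(scores, y_test), ber = ber(cm), confusion = cm,
    threshold = threshold,
    n_train = if (is.null(train)) NA_integer_ else length(train$y),
    n_test = length(y_test)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "AUC = %.4f, BER = %.4f (threshold %.4g)\n  confusion: TP=%d FP=%d TN=%d FN=%d  (n_test = %d)\n",
    x$auc, x$ber, x$threshold, x$confusion["tp"], x$confusion["fp"],
    x$confusion["tn"], x$confusion["fn"], x$n_test))
  invisible(x)
}
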