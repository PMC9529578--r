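# Knee-point (maximum-curvature) selection on the sorted coefficient curve.
#
# Implements the Kneedle procedure for a decreasing convex curve: both axes
# are min-max normalized, the curve is reflected into a concave increasing
# one, the difference between the normalized curve and the diagonal is formed,
# and the knee is the first local maximum of that difference whose subsequent
# values fall below a sensitivity-dependent threshold. Selection takes the
# strict prefix of features whose values exceed the knee value.

new_coef_curve <- function(values, names, ranking_mode) {
  ord <- order(-values, names)  # descending, lexicographic name tie-break
  structure(list(values = values[ord], names = names[ord],
                 ranking_mode = ranking_mode, knee_index = NULL,
                 selected = NULL),
            class = "coef_curve")
}

#' Sort model coefficients into a coefficient curve
#'
#' Sorts a fitted model's coefficients from high to low, by absolute magnitude
#' (default) or signed value. Ties are broken lexicographically by feature
#' name, so the ordering is deterministic. The intercept is excluded.
#'
#' Absolute mode is the default because one-hot dummy features carry protective
#' (negative) associations whose strength matters for importance; signed mode
#' ranks literally from the largest positive coefficient down.
#'
#' @param model a `penlogit` fit, or a named numeric vector of scores.
#' @param ranking_mode `"absolute"` or `"signed"`.
#' @return A `coef_curve`: `values` (nonincreasing), `names`, `ranking_mode`,
#'   plus `knee_index`/`selected` once [find_knee()] / [select_above_knee()]
#'   have been applied.
#' @export
sort_coefficients <- function(model, ranking_mode = c("absolute", "signed")) {
  ranking_mode <- match.arg(ranking_mode)
  theta <- if (inherits(model, "penlogit")) model$theta else model
  if (length(theta) == 0)
    stop("model has no coefficients to sort", call. = FALSE)
  if (is.null(names(theta)))
    stop("coefficients must be named", call. = FALSE)
  vals <- if (ranking_mode == "absolute") abs(theta) else theta
  new_coef_curve(unname(vals), names(theta), ranking_mode)
}

# Kneedle for a nonincreasing curve, 1-based index of the knee or
# NA_integer_ when no knee satisfies the sensitivity threshold.
#
# Both axes are min-max normalized and the curve is reflected into a concave
# increasing one; the difference d between it and the diagonal is formed. A
# local maximum of d is a candidate knee; it is confirmed when d subsequently
# falls below (candidate - S * mean x-spacing) before the next candidate
# re-arms the threshold. The knee is the confirmed candidate with the largest
# difference value — the extremum of the difference curve, i.e. the point of
# maximum curvature. (A streaming walk that stops at the first confirmed
# candidate instead degenerates on long noisy coefficient curves, latching
# onto a micro-bend among the top-ranked features; on pronounced elbows the
# two rules coincide.)
kneedle_decreasing <- function(y, sensitivity = 1) {
  n <- length(y)
  x <- (seq_len(n) - 1) / (n - 1)
  yt <- max(y) - y                    # reflect: now nondecreasing, concave
  rng <- max(yt) - min(yt)
  if (rng <= 0) return(NA_integer_)   # flat curve: no curvature anywhere
  yn <- (yt - min(yt)) / rng
  d <- yn - x                         # difference curve

  interior <- 2:(n - 1)
  is_lmax <- vapply(interior, function(i)
    d[i] >= d[i - 1] && d[i] >= d[i + 1], logical(1))
  is_lmin <- vapply(interior, function(i)
    d[i] <= d[i - 1] && d[i] <= d[i + 1], logical(1))
  lmax <- interior[is_lmax & !is_lmin]  # flat stretches are not bends
  if (length(lmax) == 0) return(NA_integer_)

  thr <- d[lmax] - sensitivity / (n - 1)
  upper <- c(lmax[-1] - 1L, n)          # window before the next candidate
  confirmed <- vapply(seq_along(lmax), function(j) {
    i <- lmax[j]
    i < upper[j] && any(d[(i + 1L):upper[j]] < thr[j])
  }, logical(1))
  if (!any(confirmed)) return(NA_integer_)
  cand <- lmax[confirmed]
  cand[which.max(d[cand])]
}

#' Locate the knee of a coefficient curve
#'
#' Finds the point of maximum curvature of a nonincreasing coefficient curve —
#' the point where the curve becomes flat — using the Kneedle procedure
#' (min-max normalization of both axes, difference curve against the diagonal,
#' threshold on local maxima). With the default sensitivity 1 and no smoothing
#' this matches the reference detector's defaults for a decreasing convex
#' curve.
#'
#' @param curve a `coef_curve` from [sort_coefficients()], or a nonincreasing
#'   numeric vector.
#' @param sensitivity Kneedle sensitivity S (default 1); larger values demand a
#'   more pronounced knee.
#' @return The input curve with `knee_index` set (1-based; `NA` when no knee is
#'   detected, e.g. on a perfectly linear curve). When `curve` is a bare
#'   numeric vector the index itself is returned.
#' @export
find_knee <- function(curve, sensitivity = 1) {
  bare <- !inherits(curve, "coef_curve")
  y <- if (bare) as.numeric(curve) else curve$values
  if (length(y) < 4)
    stop("need at least 4 points to locate a knee", call. = FALSE)
  if (is.unsorted(rev(y)))
    stop("curve values must be nonincreasing", call. = FALSE)
  idx <- kneedle_decreasing(y, sensitivity)
  # a knee is an interior bend: never the first or last point
  if (!is.na(idx) && (idx < 2L || idx >= length(y))) idx <- NA_integer_
  if (bare) return(idx)
  curve$knee_index <- idx
  curve
}

#' Select the features above the knee point
#'
#' Returns the features whose curve values lie strictly above the knee value
#' (ties exactly at the knee are excluded), i.e. the strict prefix of the
#' sorted curve ending before the knee.
#'
#' @param curve a `coef_curve` with `knee_index` set by [find_knee()].
#' @param quiet suppress the selection log message.
#' @return Character vector of selected feature names (empty when no knee was
#'   detected).
#' @export
select_above_knee <- function(curve, quiet = FALSE) {
  stopifnot(inherits(curve, "coef_curve"))
  if (is.null(curve$knee_index))
    stop("knee_index is unset; call find_knee() first", call. = FALSE)
  if (is.na(curve$knee_index)) {
    if (!quiet) message("no knee detected (degenerate curve); nothing selected")
    return(character(0))
  }
  kv <- curve$values[curve$knee_index]
  sel <- curve$names[curve$values > kv]
  if (!quiet)
    message(sprintf("selected %d feature(s) above knee value %.6g (index %d)",
                    length(sel), kv, curve$knee_index))
  sel
}

#' @export
print.coef_curve <- function(x, ...) {
  cat(sprintf("Coefficient curve: %d features, %s ranking", length(x$values),
              x$ranking_mode))
  if (!is.null(x$knee_index)) {
    if (is.na(x$knee_index)) cat("; no knee detected")
    else cat(sprintf("; knee at index %d (value %.6g)", x$knee_index,
                     x$values[x$knee_index]))
  }
  cat("\n")
  invisible(x)
}

#' @export
plot.coef_curve <- function(x, ...) {
  graphics::plot(seq_along(x$values), x$values, type = "b", pch = 16,
                 cex = 0.6, xlab = "rank", ylab = "coefficient value",
                 main = "Sorted coefficient curve", ...)
  if (!is.null(x$knee_index) && !is.na(x$knee_index))
    graphics::abline(v = x$knee_index, lty = 2, col = "red")
  invisible(x)
}

#' Export a coefficient curve as a data frame
#'
#' One row per feature: rank, name, value and whether it lies above the knee.
#'
#' @param curve a `coef_curve` (knee found).
#' @return A data.frame with columns `rank`, `name`, `value`, `selected`.
#' @export
curve_table <- function(curve) {
  stopifnot(inherits(curve, "coef_curve"))
  sel <- if (is.null(curve$knee_index) || is.na(curve$knee_index)) {
    rep(FALSE, length(curve$values))
  } else curve$values > curve$values[curve$knee_index]
  data.frame(rank = seq_along(curve$values), name = curve$names,
             value = curve$values, selected = sel)
}
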