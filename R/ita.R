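# Iterative thematic analysis engine.
#
# One iteration: CV-tuned lasso on the active features -> restrict to the
# lasso support -> CV-tuned ridge -> sort coefficients and locate the knee ->
# select features above the knee -> identify valid themes from the theme map
# -> evaluate on the fixed test split -> drop the top-scoring theme. The loop
# stops when an iteration selects no new features, when three consecutive
# iterations yield no new theme, or when no valid theme remains to drop.

#' Construct a theme map
#'
#' @param assignments named list mapping each variable name to a character
#'   vector of theme labels (possibly empty; a variable may belong to several
#'   themes).
#' @return A `theme_map` object.
#' @export
theme_map <- function(assignments) {
  if (length(assignments) && (is.null(names(assignments)) ||
                              any(names(assignments) == "")))
    stop("theme map assignments must be named by variable", call. = FALSE)
  assignments <- lapply(assignments, function(v) {
    v <- as.character(v)
    if (any(!nzchar(v))) stop("theme labels must be nonempty strings",
                              call. = FALSE)
    unique(v)
  })
  structure(assignments, class = "theme_map")
}

#' @export
print.theme_map <- function(x, ...) {
  labs <- unique(unlist(x))
  cat(sprintf("Theme map: %d variables, %d themes, %d unthemed variable(s)\n",
              length(x), length(labs),
              sum(lengths(x) == 0)))
  invisible(x)
}

# themes of a (possibly dummy-level) feature name: exact match first, then via
# its source variable; unknown names return NULL
themes_of <- function(name, tm, source_map = NULL) {
  if (!is.null(tm[[name]])) return(tm[[name]])
  if (!is.null(source_map) && !is.na(source_map[name]) &&
      !is.null(tm[[source_map[[name]]]]))
    return(tm[[source_map[[name]]]])
  if (name %in% names(tm) ||
      (!is.null(source_map) && !is.na(source_map[name]) &&
       source_map[[name]] %in% names(tm)))
    return(character(0))
  NULL
}

#' Identify valid themes among selected features
#'
#' A theme is valid when its selected membership reaches both an absolute
#' floor and a fraction of the selection:
#' `members >= max(min_count, ceiling(min_fraction * n_selected))` — the 5%
#' / two-variable rule. Selected features whose variable belongs to no theme
#' are reported individually as unthemed; features unknown to the theme map
#' are reported with a warning and treated as unthemed.
#'
#' @param selected character vector of selected feature names (dummy-level).
#' @param tm a [theme_map()] over source variables (or feature names).
#' @param min_fraction minimum fraction of the selection per theme
#'   (default 0.05).
#' @param min_count minimum absolute member count per theme (default 2).
#' @param source_map optional named vector mapping dummy names to source
#'   variables (as in a `design_matrix`).
#' @return List with `valid_themes` (labels), `members` (list: theme ->
#'   selected members, valid themes only), `members_all` (the same for every
#'   theme with at least one selected member), `unthemed` (selected features
#'   in no theme) and `threshold` (the member count required).
#' @export
identify_themes <- function(selected, tm, min_fraction = 0.05, min_count = 2,
                            source_map = NULL) {
  stopifnot(inherits(tm, "theme_map"))
  if (length(selected) == 0) {
    warning("empty selection: no themes to identify", call. = FALSE)
    return(list(valid_themes = character(0), members = list(),
                members_all = list(), unthemed = character(0),
                threshold = min_count))
  }
  th <- lapply(stats::setNames(selected, selected), themes_of, tm = tm,
               source_map = source_map)
  unknown <- selected[vapply(th, is.null, logical(1))]
  if (length(unknown))
    warning("features unknown to the theme map (treated as unthemed): ",
            paste(utils::head(unknown, 10), collapse = ", "), call. = FALSE)
  th[vapply(th, is.null, logical(1))] <- list(character(0))
  threshold <- max(min_count, ceiling(min_fraction * length(selected)))
  members <- list()
  for (v in selected) for (lab in th[[v]])
    members[[lab]] <- c(members[[lab]], v)
  valid <- names(members)[vapply(members, length, 0L) >= threshold]
  list(valid_themes = sort(valid), members = members[sort(valid)],
       members_all = members, unthemed = selected[lengths(th) == 0],
       threshold = threshold)
}

#' Score a theme from the coefficient curve
#'
#' Default score: the maximum coefficient magnitude among the theme's selected
#' members (`"max"`); `"mean"` and `"var"` aggregations are available. Used to
#' pick the theme to drop at the end of an iteration.
#'
#' @param members character vector of the theme's selected member features.
#' @param curve a `coef_curve` covering the members.
#' @param mode `"max"`, `"mean"` or `"var"`.
#' @return The theme score (a scalar).
#' @export
theme_score <- function(members, curve, mode = c("max", "mean", "var")) {
  mode <- match.arg(mode)
  stopifnot(inherits(curve, "coef_curve"))
  if (length(members) == 0)
    stop("theme has no selected members", call. = FALSE)
  vals <- curve$values[match(members, curve$names)]
  if (anyNA(vals))
    stop("members missing from curve: ",
         paste(members[is.na(vals)], collapse = ", "), call. = FALSE)
  switch(mode, max = max(vals), mean = mean(vals), var = stats::var(vals))
}

# top-scoring theme; ties broken by larger member count, then lexicographic
# label
choose_drop_theme <- function(members, curve, mode) {
  labs <- names(members)
  scores <- vapply(labs, function(l) theme_score(members[[l]], curve, mode), 0)
  ord <- order(-scores, -lengths(members), labs)
  labs[ord[1]]
}

#' Remove a dropped theme's variables from the active set
#'
#' A variable leaves the active set only when every theme it belongs to has
#' been dropped; variables in multiple themes survive until their last theme
#' falls, and unthemed variables are untouched by theme drops.
#'
#' @param active character vector of active feature names.
#' @param theme theme label being dropped.
#' @param tm a [theme_map()].
#' @param dropped labels of themes dropped in earlier iterations.
#' @param source_map optional dummy -> source variable map.
#' @return The reduced active set.
#' @export
drop_theme <- function(active, theme, tm, dropped = character(0),
                       source_map = NULL) {
  stopifnot(inherits(tm, "theme_map"))
  if (!theme %in% unlist(tm))
    stop("unknown theme: ", theme, call. = FALSE)
  gone <- c(dropped, theme)
  keep <- vapply(active, function(v) {
    th <- themes_of(v, tm, source_map)
    if (is.null(th) || length(th) == 0) TRUE else !all(th %in% gone)
  }, logical(1))
  active[keep]
}

#' Control parameters for the ITA loop
#'
#' @param min_fraction,min_count theme validity rule (see
#'   [identify_themes()]).
#' @param ranking_mode coefficient ranking, `"absolute"` (default) or
#'   `"signed"` (see [sort_coefficients()]).
#' @param score_mode theme score aggregation (see [theme_score()]).
#' @param k CV folds for lambda tuning (default 5).
#' @param n_lambda lambda grid size per stage (default 50).
#' @param cv_thresh,refit_thresh glmnet convergence thresholds for the fold
#'   fits and the refit at the selected lambda.
#' @param sensitivity Kneedle sensitivity (default 1).
#' @param train_fraction training share of the single train/test split.
#' @param threshold_mode,threshold BER operating point (see [evaluate()]).
#' @param max_no_new_themes consecutive no-new-theme iterations before
#'   stopping (default 3).
#' @param seed run seed driving the split, fold assignment and any other
#'   randomness.
#' @param quiet suppress progress messages.
#' @return A list of control parameters for [run_ita()].
#' @export
ita_control <- function(min_fraction = 0.05, min_count = 2,
                        ranking_mode = "absolute", score_mode = "max",
                        k = 5, n_lambda = 50, cv_thresh = 1e-6,
                        refit_thresh = 1e-8, sensitivity = 1,
                        train_fraction = 0.8,
                        threshold_mode = "balanced", threshold = 0.5,
                        max_no_new_themes = 3, seed = 1, quiet = TRUE) {
  as.list(environment())
}

#' Run the iterative thematic analysis
#'
#' Draws one stratified train/test split, then iterates: cross-validated lasso
#' on the active features, ridge refit on the lasso support, knee-point
#' selection on the sorted ridge coefficients, theme identification, held-out
#' evaluation, and removal of the top-scoring theme. Stopping is checked
#' before any drop: the loop ends when an iteration selects no feature outside
#' the union of all previously selected features (`no_new_variables`), when
#' `max_no_new_themes` consecutive iterations add no theme
#' (`no_new_themes_3x`), or when no valid theme remains to drop or the
#' iteration cap (number of distinct themes + `max_no_new_themes`) is reached
#' (`exhausted`).
#'
#' @param dm a `design_matrix` (see [one_hot()]).
#' @param tm a [theme_map()] over the source variables.
#' @param control a list from [ita_control()].
#' @return An `ita` object: `iterations` (full per-iteration trace),
#'   `all_themes` (union of valid themes across iterations, in discovery
#'   order), `stop_reason`, `selected_union`, `dropped_themes`, plus the
#'   inputs needed to replay the trace.
#' @export
run_ita <- function(dm, tm, control = ita_control()) {
  stopifnot(inherits(dm, "design_matrix"), inherits(tm, "theme_map"))
  if (length(unique(dm$y)) < 2) stop("outcome has a single class", call. = FALSE)
  split <- train_test_split(dm, control$train_fraction, seed = control$seed,
                            stratified = TRUE)
  n_theme_labels <- length(unique(unlist(tm)))
  cap <- max(1L, n_theme_labels + control$max_no_new_themes)

  state <- list(active = dm$feature_names, seen_vars = character(0),
                seen_themes = character(0), dropped = character(0),
                streak = 0L)
  iterations <- list()
  stop_reason <- "exhausted"

  for (i in seq_len(cap)) {
    step <- ita_iteration(i, state, split, tm, dm$source_map, control)
    iterations[[i]] <- step$record
    state <- step$state
    if (!is.null(step$stop)) { stop_reason <- step$stop; break }
  }

  structure(list(
    iterations = iterations,
    all_themes = unique(unlist(lapply(iterations, `[[`, "valid_themes"))),
    stop_reason = stop_reason,
    selected_union = state$seen_vars,
    dropped_themes = state$dropped,
    control = control, theme_map = tm,
    split = list(train_idx = split$train_idx, test_idx = split$test_idx)
  ), class = "ita")
}

# One ITA iteration; returns the updated state, the trace record, and the
# stop reason if the loop must end here.
ita_iteration <- function(i, state, split, tm, source_map, control) {
  active <- state$active
  rec <- list(iteration_number = i, active_variables = active,
              lasso_support = character(0), lasso_lambda = NA_real_,
              ridge_model = NULL, ridge_lambda = NA_real_, curve = NULL,
              selected = character(0), valid_themes = character(0),
              theme_members = list(), new_themes = character(0),
              unthemed = character(0),
              dropped_theme = NA_character_, metrics = NULL, note = NULL)
  done <- function(stop = NULL, note = NULL) {
    rec$note <- note
    if (!is.null(note) && !control$quiet) message(sprintf("[iter %d] %s", i, note))
    list(state = state, record = rec, stop = stop)
  }

  if (length(active) < 2)
    return(done("no_new_variables", "fewer than 2 active features"))
  Xtr <- split$train$X[, active, drop = FALSE]
  ytr <- split$train$y

  # lasso reduction, lambda re-tuned on the current active set
  l1 <- penlogit_cv(Xtr, ytr, "l1",
                    grid = lambda_grid(Xtr, ytr, "l1", control$n_lambda),
                    k = control$k, thresh = control$cv_thresh,
                    refit_thresh = control$refit_thresh,
                    seed = derive_seed(control$seed, sprintf("l1-%d", i)))
  support <- nonzero_features(l1$model)
  rec$lasso_support <- support
  rec$lasso_lambda <- l1$cv$lambda_star
  if (length(support) == 0)
    return(done("no_new_variables", "empty lasso support"))

  if (length(support) < 4) {
    # too few survivors to locate a knee; nothing selectable
    return(done("no_new_variables",
                sprintf("lasso support of %d features is below the 4 needed for knee detection",
                        length(support))))
  }

  # ridge refit on the support, lambda re-tuned
  Xs <- Xtr[, support, drop = FALSE]
  l2 <- penlogit_cv(Xs, ytr, "l2",
                    grid = lambda_grid(Xs, ytr, "l2", control$n_lambda),
                    k = control$k, thresh = control$cv_thresh,
                    refit_thresh = control$refit_thresh,
                    seed = derive_seed(control$seed, sprintf("l2-%d", i)))
  rec$ridge_model <- l2$model
  rec$ridge_lambda <- l2$cv$lambda_star

  curve <- find_knee(sort_coefficients(l2$model, control$ranking_mode),
                     control$sensitivity)
  rec$curve <- curve
  selected <- select_above_knee(curve, quiet = TRUE)
  rec$selected <- selected
  rec$metrics <- evaluate(l2$model, split$test, train = split$train,
                          threshold_mode = control$threshold_mode,
                          threshold = control$threshold)
  if (length(selected) == 0)
    return(done("no_new_variables", "no features above the knee"))

  ids <- suppressWarnings(
    identify_themes(selected, tm, control$min_fraction, control$min_count,
                    source_map))
  rec$valid_themes <- ids$valid_themes
  rec$theme_members <- ids$members
  rec$unthemed <- ids$unthemed
  rec$new_themes <- setdiff(ids$valid_themes, state$seen_themes)
  new_vars <- setdiff(selected, state$seen_vars)
  state$seen_vars <- union(state$seen_vars, selected)
  state$seen_themes <- union(state$seen_themes, ids$valid_themes)

  # stopping is checked before any theme drop
  if (length(new_vars) == 0)
    return(done("no_new_variables", "no new variables selected"))
  state$streak <- if (length(rec$new_themes) == 0) state$streak + 1L else 0L
  if (state$streak >= control$max_no_new_themes)
    return(done("no_new_themes_3x",
                sprintf("no new themes for %d consecutive iterations",
                        state$streak)))

  # themes persist once identified: the drop pool is every theme found so far
  # (this or an earlier iteration), not yet dropped, with at least one member
  # in the current selection
  droppable <- setdiff(intersect(state$seen_themes, names(ids$members_all)),
                       state$dropped)
  if (length(droppable) == 0)
    return(done("exhausted", "no identified theme left to drop"))
  top <- choose_drop_theme(ids$members_all[droppable], curve,
                           control$score_mode)
  rec$dropped_theme <- top
  state$dropped <- c(state$dropped, top)
  state$active <- drop_theme(active, top, tm, state$dropped[-length(state$dropped)],
                             source_map)
  if (!control$quiet)
    message(sprintf("[iter %d] %d selected, themes {%s}, dropped '%s'", i,
                    length(selected), paste(ids$valid_themes, collapse = ", "),
                    top))
  list(state = state, record = rec, stop = NULL)
}

#' Replay the logged ITA trace
#'
#' Recomputes every iteration from the logged active sets and seeds against
#' the same design matrix and theme map, rebuilding the final result; used to
#' verify that the trace fully determines the outcome.
#'
#' @param result an `ita` object.
#' @param dm the `design_matrix` the result was computed from.
#' @return A reconstructed `ita` object (identical to `result` for a faithful
#'   trace).
#' @export
replay_trace <- function(result, dm) {
  stopifnot(inherits(result, "ita"))
  control <- result$control
  tm <- result$theme_map
  split <- train_test_split(dm, control$train_fraction, seed = control$seed,
                            stratified = TRUE)
  state <- list(active = dm$feature_names, seen_vars = character(0),
                seen_themes = character(0), dropped = character(0),
                streak = 0L)
  iterations <- list()
  stop_reason <- "exhausted"
  for (i in seq_along(result$iterations)) {
    logged <- result$iterations[[i]]$active_variables
    if (!identical(logged, state$active))
      stop("trace mismatch at iteration ", i, ": active set differs",
           call. = FALSE)
    step <- ita_iteration(i, state, split, tm, dm$source_map, control)
    iterations[[i]] <- step$record
    state <- step$state
    if (!is.null(step$stop)) { stop_reason <- step$stop; break }
  }
  structure(list(
    iterations = iterations,
    all_themes = unique(unlist(lapply(iterations, `[[`, "valid_themes"))),
    stop_reason = stop_reason,
    selected_union = state$seen_vars,
    dropped_themes = state$dropped,
    control = control, theme_map = tm,
    split = list(train_idx = split$train_idx, test_idx = split$test_idx)
  ), class = "ita")
}

#' @export
print.ita <- function(x, ...) {
  cat(sprintf(
    "Iterative thematic analysis: %d iteration(s), %d theme(s), stop reason: %s\n",
    length(x$iterations), length(x$all_themes), x$stop_reason))
  cat("Themes:", if (length(x$all_themes)) paste(x$all_themes, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' @export
summary.ita <- function(object, ...) {
  rows <- lapply(object$iterations, function(it) {
    data.frame(
      iteration = it$iteration_number,
      n_active = length(it$active_variables),
      n_support = length(it$lasso_support),
      n_selected = length(it$selected),
      valid_themes = paste(it$valid_themes, collapse = ","),
      new_themes = paste(it$new_themes, collapse = ","),
      n_unthemed = length(it$unthemed),
      dropped = it$dropped_theme,
      auc = if (is.null(it$metrics)) NA_real_ else it$metrics$auc,
      ber = if (is.null(it$metrics)) NA_real_ else it$metrics$ber)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary.ita", "data.frame")
  attr(out, "stop_reason") <- object$stop_reason
  out
}

#' @export
print.summary.ita <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat("stop reason:", attr(x, "stop_reason"), "\n")
  invisible(x)
}

#' @export
plot.ita <- function(x, iteration = 1, ...) {
  it <- x$iterations[[iteration]]
  if (is.null(it$curve)) stop("iteration has no coefficient curve", call. = FALSE)
  plot(it$curve, ...)
  graphics::title(sub = sprintf("iteration %d", iteration))
  invisible(x)
}

#' Themes-by-members report table
#'
#' One row per (theme, member feature) pair across all iterations, in the
#' shape of a themes-times-variables summary table, with the iteration in
#' which the theme was first found.
#'
#' @param result an `ita` object.
#' @return A data.frame with columns `theme`, `member`, `first_iteration`.
#' @export
report_table <- function(result) {
  stopifnot(inherits(result, "ita"))
  seen <- character(0)
  rows <- list()
  for (it in result$iterations) {
    for (lab in setdiff(it$valid_themes, seen)) {
      rows[[length(rows) + 1]] <- data.frame(
        theme = lab, member = it$theme_members[[lab]],
        first_iteration = it$iteration_number)
    }
    seen <- union(seen, it$valid_themes)
  }
  if (!length(rows)) return(data.frame(theme = character(0),
                                       member = character(0),
                                       first_iteration = integer(0)))
  do.call(rbind, rows)
}
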