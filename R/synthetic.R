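# Synthetic DHS-like survey generator with planted theme-structured effects
# and a rare binary outcome.
#
# Mechanism: each theme has one standard-normal latent factor per respondent;
# each of the theme's variables thresholds a noisy copy of that factor
# (correlation sqrt within_theme_correlation between variables of one theme)
# into equal-probability categories, giving block-correlated dummies like real
# questionnaire modules. Noise variables threshold independent normals and
# carry exactly zero effect. Redundant variables are deterministic coarsened
# recodings (pairwise category merges) of theme variables. The outcome follows
# a sparse logistic model over the dummy scale whose nonzero effects cluster
# within the planted themes; the intercept is calibrated by bisection so the
# mean outcome probability hits the target prevalence.

#' Configuration for the synthetic survey generator
#'
#' Defaults describe the reference study conditions used throughout the test
#' suite: 20,000 respondents, 8 planted themes of 5 four-category variables
#' each (200 signal dummies) with per-theme log-odds magnitudes evenly spaced
#' over 0.5-1.0, 50 pure-noise variables (200 noise dummies), 5 redundant
#' recodings, within-theme correlation 0.3 and 2% outcome prevalence.
#'
#' @param n_respondents number of respondents.
#' @param n_themes number of planted themes.
#' @param vars_per_theme variables per theme.
#' @param categories_per_var categories per variable (>= 2).
#' @param n_noise_vars variables with exactly zero true effect.
#' @param n_redundant_vars deterministic coarsened recodings of theme
#'   variables.
#' @param theme_effects per-theme log-odds magnitude (length `n_themes`); the
#'   dummy-scale effects of a theme's variables range linearly from minus to
#'   plus this value across the ordered categories.
#' @param within_theme_correlation latent correlation of variables within a
#'   theme, in \[0, 1).
#' @param target_prevalence outcome prevalence, in (0, 0.5).
#' @param noise_theme_size noise variables are grouped into pseudo-themes of
#'   this size in the theme map (they emulate coherent questionnaire modules
#'   that carry no signal); 0 leaves noise variables unthemed.
#' @param seed integer seed; all generator randomness derives from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_respondents = 20000,
                             n_themes = 8,
                             vars_per_theme = 5,
                             categories_per_var = 4,
                             n_noise_vars = 50,
                             n_redundant_vars = 5,
                             theme_effects = seq(0.5, 1.0,
                                                 length.out = n_themes),
                             within_theme_correlation = 0.3,
                             target_prevalence = 0.02,
                             noise_theme_size = 5,
                             seed = 1) {
  cfg <- list(n_respondents = n_respondents, n_themes = n_themes,
              vars_per_theme = vars_per_theme,
              categories_per_var = categories_per_var,
              n_noise_vars = n_noise_vars,
              n_redundant_vars = n_redundant_vars,
              theme_effects = theme_effects,
              within_theme_correlation = within_theme_correlation,
              target_prevalence = target_prevalence,
              noise_theme_size = noise_theme_size, seed = seed)
  with(cfg, {
    stopifnot(n_respondents >= 1, n_themes >= 1, vars_per_theme >= 1,
              categories_per_var >= 2, n_noise_vars >= 0,
              n_redundant_vars >= 0,
              length(theme_effects) == n_themes,
              within_theme_correlation >= 0, within_theme_correlation < 1,
              target_prevalence > 0, target_prevalence < 0.5)
  })
  if (cfg$n_redundant_vars > cfg$n_themes * cfg$vars_per_theme)
    stop("more redundant variables than parent theme variables", call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

# Bisection for the intercept c solving mean(sigmoid(c + lp)) = target.
calibrate_intercept <- function(lp, target, tol = 1e-10) {
  if (!all(is.finite(lp)))
    stop("invalid config: non-finite linear predictor (infinite effects?)",
         call. = FALSE)
  lo <- -60; hi <- 60
  f <- function(c) mean(sigmoid(c + lp)) - target
  if (f(lo) > 0 || f(hi) < 0)
    stop("invalid config: prevalence target unattainable", call. = FALSE)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Generate a synthetic survey
#'
#' @param config a [synthetic_config()].
#' @return A `synthetic_survey`: `table` (data.frame of categorical factors),
#'   `outcome` (0/1), `true_theta` (named dummy-scale log-odds, exactly zero
#'   for noise and redundant variables), `true_theme_map` (a [theme_map()];
#'   redundant variables inherit their parent's themes, noise variables carry
#'   pseudo-theme labels `noise_theme*`), `planted_themes` (labels of the
#'   signal-bearing themes), `intercept`, `linear_predictor` and the `config`.
#'   Deterministic given `config$seed`.
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!all(is.finite(config$theme_effects)))
    stop("invalid config: theme_effects must be finite", call. = FALSE)
  n <- config$n_respondents
  k <- config$categories_per_var
  rho <- config$within_theme_correlation
  cuts <- stats::qnorm(seq_len(k - 1) / k)
  cat_labels <- paste0("c", seq_len(k))
  # dummy-scale effect of category j in a theme with magnitude a:
  # linear scores spanning [-a, a]
  cat_scores <- (2 * (seq_len(k) - 1) / (k - 1) - 1)

  cols <- list(); theta <- numeric(0); tm <- list()
  lp <- numeric(n)
  planted <- paste0("theme", seq_len(config$n_themes))

  with_seed(derive_seed(config$seed, "survey-latents"), {
    for (t in seq_len(config$n_themes)) {
      f <- stats::rnorm(n)
      a <- config$theme_effects[t]
      for (j in seq_len(config$vars_per_theme)) {
        z <- sqrt(rho) * f + sqrt(1 - rho) * stats::rnorm(n)
        cat_idx <- findInterval(z, cuts) + 1L
        v <- sprintf("theme%d_q%d", t, j)
        cols[[v]] <- factor(cat_labels[cat_idx], levels = cat_labels)
        eff <- stats::setNames(a * cat_scores, paste0(v, "=", cat_labels))
        theta <- c(theta, eff)
        lp <- lp + a * cat_scores[cat_idx]
        tm[[v]] <- planted[t]
      }
    }
    for (i in seq_len(config$n_noise_vars)) {
      z <- stats::rnorm(n)
      v <- sprintf("noise_q%d", i)
      cols[[v]] <- factor(cat_labels[findInterval(z, cuts) + 1L],
                          levels = cat_labels)
      theta <- c(theta,
                 stats::setNames(rep(0, k), paste0(v, "=", cat_labels)))
      tm[[v]] <- if (config$noise_theme_size > 0)
        sprintf("noise_theme%d", (i - 1) %/% config$noise_theme_size + 1)
      else character(0)
    }
  })

  # redundant variables: deterministic pairwise category merges of parents
  theme_vars <- grep("^theme", names(cols), value = TRUE)
  merged_labels <- paste0("m", (seq_len(k) - 1) %/% 2 + 1)
  for (i in seq_len(config$n_redundant_vars)) {
    parent <- theme_vars[i]
    v <- paste0(parent, "_coarse")
    cols[[v]] <- factor(merged_labels[as.integer(cols[[parent]])],
                        levels = unique(merged_labels))
    theta <- c(theta, stats::setNames(rep(0, length(unique(merged_labels))),
                                      paste0(v, "=", unique(merged_labels))))
    tm[[v]] <- tm[[parent]]
  }

  b0 <- calibrate_intercept(lp, config$target_prevalence)
  outcome <- with_seed(derive_seed(config$seed, "survey-outcome"),
                       stats::rbinom(n, 1, sigmoid(b0 + lp)))

  structure(list(
    table = as.data.frame(cols, optional = TRUE),
    outcome = outcome, true_theta = theta, true_theme_map = theme_map(tm),
    planted_themes = planted, intercept = b0, linear_predictor = lp,
    config = config
  ), class = "synthetic_survey")
}

#' @export
print.synthetic_survey <- function(x, ...) {
  cat(sprintf(
    "Synthetic survey: %d respondents x %d variables; %d planted themes; prevalence %.3f%% (target %.3f%%)\n",
    nrow(x$table), ncol(x$table), x$config$n_themes, 100 * mean(x$outcome),
    100 * x$config$target_prevalence))
  invisible(x)
}

#' Catalog for a synthetic survey
#'
#' Marks every generated variable `analysis` except the redundant recodings
#' (role `redundant`) and adds the outcome column.
#'
#' @param survey a `synthetic_survey`.
#' @param outcome_name name given to the outcome column (default
#'   `"uses_iud"`).
#' @return A [variable_catalog()].
#' @export
survey_catalog <- function(survey, outcome_name = "uses_iud") {
  stopifnot(inherits(survey, "synthetic_survey"))
  roles <- stats::setNames(
    ifelse(grepl("_coarse$", names(survey$table)), "redundant", "analysis"),
    names(survey$table))
  roles[outcome_name] <- "outcome"
  variable_catalog(roles)
}

#' Encode a synthetic survey into a design matrix
#'
#' Convenience chain: attach the outcome, screen by the survey catalog
#' (dropping redundant recodings) and one-hot encode.
#'
#' @inheritParams survey_catalog
#' @return A `design_matrix` (see [one_hot()]).
#' @export
as_design_matrix <- function(survey, outcome_name = "uses_iud") {
  stopifnot(inherits(survey, "synthetic_survey"))
  tab <- survey$table
  tab[[outcome_name]] <- survey$outcome
  cat <- survey_catalog(survey, outcome_name)
  one_hot(screen_variables(tab, cat, quiet = TRUE), outcome_name, quiet = TRUE)
}

#' Write a synthetic survey to disk as pipeline-ready fixtures
#'
#' Emits `table.csv` (respondent table including the outcome column),
#' `catalog.yaml` (variable roles) and `themes.yaml` (variable -> theme
#' assignments). The files round-trip losslessly through [utils::read.csv()],
#' [read_catalog()] and [read_theme_map()].
#'
#' @param survey a `synthetic_survey`.
#' @param path directory to write into (created if needed).
#' @param outcome_name name of the outcome column.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_fixtures <- function(survey, path, outcome_name = "uses_iud") {
  stopifnot(inherits(survey, "synthetic_survey"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory ", path, call. = FALSE)
  tab <- survey$table
  tab[[outcome_name]] <- survey$outcome
  files <- c(table = file.path(path, "table.csv"),
             catalog = file.path(path, "catalog.yaml"),
             themes = file.path(path, "themes.yaml"))
  utils::write.csv(tab, files["table"], row.names = FALSE)
  write_catalog(survey_catalog(survey, outcome_name), files["catalog"])
  write_theme_map(survey$true_theme_map, files["themes"])
  invisible(files)
}
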