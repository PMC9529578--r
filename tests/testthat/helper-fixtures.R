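# Shared fixtures, built in code.

# Small, fast synthetic survey for unit tests.
small_survey <- function(seed = 1, n = 4000, prevalence = 0.1) {
  generate_survey(synthetic_config(
    n_respondents = n, n_themes = 2, vars_per_theme = 3,
    categories_per_var = 3, n_noise_vars = 6, n_redundant_vars = 2,
    theme_effects = c(1.2, 1.0), within_theme_correlation = 0.3,
    target_prevalence = prevalence, noise_theme_size = 3, seed = seed))
}

# Tiny deterministic design matrix for contract tests.
tiny_design <- function(n = 200, p = 4, seed = 42, prevalence = 0.3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  eta <- X %*% c(1, -1, rep(0, p - 2)) + qlogis(prevalence)
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  structure(list(X = X, y = y, feature_names = colnames(X),
                 source_map = stats::setNames(colnames(X), colnames(X)),
                 outcome_name = "y"),
            class = "design_matrix")
}

# Threshold a latent vector into k equal-probability ordered categories.
cut_latent <- function(z, k = 3) {
  cuts <- qnorm(seq_len(k - 1) / k)
  factor(paste0("c", findInterval(z, cuts) + 1), paste0("c", seq_len(k)))
}

# A survey engineered to walk through the canonical three-iteration structure:
# four themes discovered in iteration 1, three more plus one unthemed variable
# in iteration 2, and no new variables in iteration 3.
#
# Construction: a dominant latent trait L drives the outcome strongly and is
# measured well by the two continuous variables of theme "shared_fp_goals",
# and only coarsely (categorized, low loading) by the variables of three
# proxy themes and one unthemed variable (television access). While the
# direct measures are in the model the proxies stay below the knee; once the
# top theme is dropped, the proxies become the only carriers of L's signal
# and surface together. Three further themes load on independent factors with
# intermediate effects so they clear the knee from iteration 1.
masking_scenario_survey <- function(seed = 303, n = 10000) {
  with_seed <- get("with_seed", envir = asNamespace("itasurvey"))
  with_seed(seed, {
    L <- rnorm(n); F2 <- rnorm(n); F3 <- rnorm(n); F4 <- rnorm(n)
    meas <- function(f, r) sqrt(r) * f + sqrt(1 - r) * rnorm(n)
    cols <- list()
    tm <- list()
    add <- function(name, f, r, themes) {
      cols[[name]] <<- cut_latent(meas(f, r), k = 3)
      tm[[name]] <<- themes
    }
    # continuous measures of L with distinct fidelities, so the ridge does
    # not split their shared effect evenly
    for (j in 1:2) {
      cols[[sprintf("goal_q%d", j)]] <- meas(L, c(0.95, 0.75)[j])
      tm[[sprintf("goal_q%d", j)]] <- "shared_fp_goals"
    }
    for (j in 1:3) add(sprintf("counsel_q%d", j), F2, 0.90, "fp_counseling")
    for (j in 1:3) add(sprintf("fertpref_q%d", j), F3, 0.90, "fertility_preference")
    for (j in 1:3) add(sprintf("contruse_q%d", j), F4, 0.90, "contraceptive_use")
    for (j in 1:2) add(sprintf("knowledge_q%d", j), L, 0.35, "contraceptive_knowledge")
    for (j in 1:2) add(sprintf("ses_q%d", j), L, 0.35, "ses")
    for (j in 1:2) add(sprintf("mch_q%d", j), L, 0.35, "mch_services")
    add("tv_access", L, 0.35, character(0))
    for (j in 1:30) add(sprintf("noise_q%d", j), rnorm(n), 1, character(0))
    eta <- 3.6 * L + 2.0 * F2 + 1.9 * F3 + 1.8 * F4
    b0 <- uniroot(function(b) mean(plogis(b + eta)) - 0.08, c(-30, 10))$root
    y <- rbinom(n, 1, plogis(b0 + eta))
    tab <- as.data.frame(cols, optional = TRUE)
    tab$uses_iud <- y
    list(dm = one_hot(tab, "uses_iud", quiet = TRUE),
         tm = theme_map(tm))
  })
}
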