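test_that("theme validity follows the 5-percent / two-variable rule", {
  tm <- theme_map(list(v1 = "A", v2 = "A", v3 = "B", v4 = character(0)))
  # 20 selected, theme with 2 members: 2 >= max(2, ceiling(1)) -> valid
  sel20 <- c("v1", "v2", paste0("x", 1:18))
  tm20 <- theme_map(c(list(v1 = "A", v2 = "A"),
                      stats::setNames(rep(list(character(0)), 18),
                                      paste0("x", 1:18))))
  ids <- identify_themes(sel20, tm20)
  expect_equal(ids$valid_themes, "A")
  expect_equal(ids$threshold, 2)
  # 100 selected, theme with 4 members: 4 < max(2, 5) -> invalid
  tm100 <- theme_map(c(stats::setNames(rep(list("T"), 4), paste0("t", 1:4)),
                       stats::setNames(rep(list(character(0)), 96),
                                       paste0("x", 1:96))))
  ids100 <- identify_themes(c(paste0("t", 1:4), paste0("x", 1:96)), tm100)
  expect_length(ids100$valid_themes, 0L)
  expect_equal(ids100$threshold, 5)
  expect_equal(length(ids100$members_all$T), 4L)
  # selected variables with no theme are reported individually as unthemed
  ids2 <- identify_themes(c("v1", "v2", "v4"), tm)
  expect_equal(ids2$unthemed, "v4")
  # unknown variables are surfaced, not silently ignored
  expect_warning(identify_themes(c("v1", "v2", "mystery"), tm), "mystery")
  expect_warning(out <- identify_themes(character(0), tm), "empty selection")
  expect_length(out$valid_themes, 0L)
})

test_that("dummy-level features inherit themes through the source map", {
  tm <- theme_map(list(wealth = "ses", edu = "ses", tv = character(0)))
  smap <- stats::setNames(c("wealth", "wealth", "edu", "tv"),
                          c("wealth=high", "wealth=low", "edu=sec", "tv=yes"))
  ids <- identify_themes(c("wealth=high", "wealth=low", "edu=sec", "tv=yes"),
                         tm, source_map = smap)
  expect_equal(ids$valid_themes, "ses")
  expect_setequal(ids$members$ses, c("wealth=high", "wealth=low", "edu=sec"))
  expect_equal(ids$unthemed, "tv=yes")
})

test_that("theme scores aggregate member coefficients as specified", {
  cv <- sort_coefficients(c(a = 0.9, b = 0.4, c = 0.2, d = 0.1))
  expect_equal(theme_score(c("a", "b"), cv, "max"), 0.9)
  expect_equal(theme_score(c("a", "b"), cv, "mean"), 0.65)
  expect_equal(theme_score(c("a", "b"), cv, "var"), stats::var(c(0.9, 0.4)))
  expect_error(theme_score(character(0), cv), "no selected members")
  expect_error(theme_score("zz", cv), "missing from curve")
  # two themes sharing their top member tie on score; the tie breaks toward
  # the larger theme, then lexicographically
  members <- list(B = c("a", "b"), A = "a", C = c("a", "c"))
  pick <- itasurvey:::choose_drop_theme(members, cv, "max")
  expect_equal(pick, "B")  # same score 0.9; B and C have 2 members; B < C
})

test_that("variables leave the active set only when their last theme falls", {
  tm <- theme_map(list(p = "A", q = c("A", "B"), r = "B", s = character(0)))
  active <- c("p", "q", "r", "s")
  a1 <- drop_theme(active, "A", tm)
  expect_setequal(a1, c("q", "r", "s"))  # q survives via B; s untouched
  a2 <- drop_theme(a1, "B", tm, dropped = "A")
  expect_setequal(a2, "s")               # q's last theme fell
  expect_error(drop_theme(active, "Z", tm), "unknown theme")
})

test_that("a single planted theme is found and the loop ends quickly", {
  sv <- generate_survey(synthetic_config(
    n_respondents = 5000, n_themes = 1, vars_per_theme = 5,
    categories_per_var = 3, n_noise_vars = 10, n_redundant_vars = 0,
    theme_effects = 1.5, target_prevalence = 0.1, noise_theme_size = 0,
    seed = 71))
  dm <- as_design_matrix(sv)
  res <- run_ita(dm, sv$true_theme_map, ita_control(seed = 71, n_lambda = 20))
  expect_s3_class(res, "ita")
  expect_true("theme1" %in% res$all_themes)
  expect_equal(res$iterations[[1]]$valid_themes, "theme1")
  expect_lte(length(res$iterations), 2L)
})

test_that("an all-empty theme map yields unthemed selections and exhaustion", {
  sv <- generate_survey(synthetic_config(
    n_respondents = 5000, n_themes = 1, vars_per_theme = 5,
    categories_per_var = 3, n_noise_vars = 10, n_redundant_vars = 0,
    theme_effects = 1.5, target_prevalence = 0.1, noise_theme_size = 0,
    seed = 72))
  dm <- as_design_matrix(sv)
  empty_tm <- theme_map(stats::setNames(
    rep(list(character(0)), ncol(sv$table)), names(sv$table)))
  res <- run_ita(dm, empty_tm, ita_control(seed = 72, n_lambda = 20))
  expect_equal(res$stop_reason, "exhausted")
  expect_length(res$all_themes, 0L)
  it1 <- res$iterations[[1]]
  expect_gt(length(it1$unthemed), 0L)
  expect_equal(sort(it1$unthemed), sort(it1$selected))
  expect_length(res$iterations, 1L)
})

test_that("the trace is complete and each iteration is internally consistent", {
  sv <- small_survey(seed = 73, n = 5000, prevalence = 0.08)
  dm <- as_design_matrix(sv)
  res <- run_ita(dm, sv$true_theme_map, ita_control(seed = 73, n_lambda = 20))
  expect_true(res$stop_reason %in%
                c("no_new_variables", "no_new_themes_3x", "exhausted"))
  n_labels <- length(unique(unlist(sv$true_theme_map)))
  expect_lte(length(res$iterations), n_labels + 3L)
  prev_active <- dm$feature_names
  dropped_so_far <- character(0)
  for (it in res$iterations) {
    expect_identical(it$active_variables, prev_active)
    expect_true(all(it$selected %in% it$lasso_support))
    expect_true(all(it$lasso_support %in% it$active_variables))
    expect_true(all(it$new_themes %in% it$valid_themes))
    if (!is.na(it$dropped_theme)) {
      after <- drop_theme(it$active_variables, it$dropped_theme,
                          sv$true_theme_map, dropped = dropped_so_far,
                          source_map = dm$source_map)
      # the active set strictly shrinks whenever a theme is dropped
      expect_lt(length(after), length(it$active_variables))
      dropped_so_far <- c(dropped_so_far, it$dropped_theme)
      prev_active <- after
    }
    if (!is.null(it$metrics)) {
      expect_gte(it$metrics$auc, 0)
      expect_lte(it$metrics$auc, 1)
    }
  }
  expect_setequal(res$selected_union,
                  unique(unlist(lapply(res$iterations, `[[`, "selected"))))
})

test_that("replaying the logged trace reproduces the result exactly", {
  sv <- small_survey(seed = 74, n = 4000, prevalence = 0.08)
  dm <- as_design_matrix(sv)
  res <- run_ita(dm, sv$true_theme_map, ita_control(seed = 74, n_lambda = 15))
  rep_ <- replay_trace(res, dm)
  expect_identical(summary(res), summary(rep_))
  expect_identical(res$all_themes, rep_$all_themes)
  expect_identical(res$stop_reason, rep_$stop_reason)
  expect_identical(res$selected_union, rep_$selected_union)
  expect_identical(lapply(res$iterations, `[[`, "selected"),
                   lapply(rep_$iterations, `[[`, "selected"))
  expect_identical(lapply(res$iterations, function(i) i$ridge_model$theta),
                   lapply(rep_$iterations, function(i) i$ridge_model$theta))
})

test_that("summary and report tables expose the per-iteration structure", {
  sv <- small_survey(seed = 75, n = 4000, prevalence = 0.08)
  dm <- as_design_matrix(sv)
  res <- run_ita(dm, sv$true_theme_map, ita_control(seed = 75, n_lambda = 15))
  sm <- summary(res)
  expect_s3_class(sm, "data.frame")
  expect_equal(nrow(sm), length(res$iterations))
  expect_true(all(c("iteration", "n_selected", "dropped", "auc", "ber") %in%
                    names(sm)))
  tab <- report_table(res)
  if (length(res$all_themes)) {
    expect_setequal(unique(tab$theme), res$all_themes)
    expect_true(all(tab$member %in% res$selected_union))
  }
})
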