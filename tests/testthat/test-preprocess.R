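make_catalog <- function(roles, rules = NULL) {
  variable_catalog(c(roles, uses_iud = "outcome"), rules)
}

test_that("screening drops irrelevant, endogenous and redundant variables", {
  tab <- data.frame(id = 1:6, ever_iud = c(1, 0, 0, 1, 0, 0),
                    age = c(25, 31, 19, 42, 37, 29),
                    age_group = c("20s", "30s", "teen", "40s", "30s", "20s"),
                    parity = c(0, 1, 2, 3, 4, 7),
                    uses_iud = c(1, 0, 0, 1, 0, 0))
  cat_ <- make_catalog(c(id = "irrelevant", ever_iud = "endogenous",
                         age = "analysis", age_group = "redundant",
                         parity = "analysis"))
  out <- screen_variables(tab, cat_, quiet = TRUE)
  expect_setequal(names(out), c("age", "parity", "uses_iud"))
  expect_false(any(c("id", "ever_iud", "age_group") %in% names(out)))
  # the continuous age survives while its categorical duplicate is screened
  expect_true("age" %in% names(out))
  # exclusions are logged with their role
  expect_message(screen_variables(tab, cat_), "ever_iud.*endogenous")
  # identity when everything is analysis
  all_cat <- variable_catalog(c(stats::setNames(
    rep("analysis", 5), names(tab)[1:5]), uses_iud = "outcome"))
  expect_identical(names(screen_variables(tab, all_cat, quiet = TRUE)),
                   names(tab))
  # uncataloged columns are a hard error naming the column
  tab$extra <- 1
  expect_error(screen_variables(tab, cat_), "extra")
})

test_that("recategorization applies the standard parity scheme", {
  tab <- data.frame(parity = c(0, 1, 2, 3, 4, 7), other = letters[1:6],
                    uses_iud = c(0, 1, 0, 1, 0, 0))
  rules <- list(parity = list(
    list(label = "0", values = 0), list(label = "1", values = 1),
    list(label = "2", values = 2), list(label = "3+", min = 3)))
  cat_ <- make_catalog(c(parity = "analysis", other = "analysis"), rules)
  out <- recategorize(tab, cat_)
  expect_equal(as.character(out$parity), c("0", "1", "2", "3+", "3+", "3+"))
  expect_equal(levels(out$parity), c("0", "1", "2", "3+"))
  # unruled variables pass through untouched
  expect_identical(out$other, tab$other)
  # a second application is the identity (idempotent chain)
  expect_identical(recategorize(out, cat_), out)
})

test_that("rule violations are rejected with informative errors", {
  # overlap between explicit value sets: load-time rejection
  expect_error(make_catalog(c(x = "analysis"), list(x = list(
    list(label = "a", values = c(1, 2)), list(label = "b", values = c(2, 3))))),
    "overlapping")
  # overlap between ranges
  expect_error(make_catalog(c(x = "analysis"), list(x = list(
    list(label = "lo", min = 0, max = 5), list(label = "hi", min = 5)))),
    "overlapping")
  # value inside a range
  expect_error(make_catalog(c(x = "analysis"), list(x = list(
    list(label = "a", values = 3), list(label = "b", min = 0, max = 10)))),
    "overlapping")
  # unmatched observed value: apply-time error listing the offender
  cat_ <- make_catalog(c(x = "analysis"),
                       list(x = list(list(label = "lo", max = 5))))
  tab <- data.frame(x = c(1, 99), uses_iud = c(0, 1))
  expect_error(recategorize(tab, cat_), "99")
})

test_that("catalog structural invariants hold", {
  expect_error(variable_catalog(c(a = "analysis")), "outcome")
  expect_error(variable_catalog(c(a = "outcome", b = "outcome")), "outcome")
  expect_error(variable_catalog(c(a = "predictor", b = "outcome")),
               "unknown roles")
  expect_error(variable_catalog(c(a = "outcome"),
                                list(zz = list(list(label = "x", values = 1)))),
               "uncataloged")
})

test_that("one-hot encoding expands categoricals fully and passes continuous through", {
  tab <- data.frame(
    color = c("red", "blue", "green", "red", "blue"),
    flag = c("y", "n", "y", "y", "n"),
    age = c(20, 30, 40, 50, 60),
    uses_iud = c(1, 0, 0, 1, 0))
  dm <- one_hot(tab, "uses_iud", quiet = TRUE)
  # 3-category -> 3 dummies, 2-category -> 2 dummies, continuous unchanged
  expect_setequal(colnames(dm$X),
                  c("color=blue", "color=green", "color=red",
                    "flag=n", "flag=y", "age"))
  expect_equal(unname(rowSums(dm$X[, grep("^color=", colnames(dm$X))])),
               rep(1, 5))
  expect_equal(unname(rowSums(dm$X[, grep("^flag=", colnames(dm$X))])),
               rep(1, 5))
  expect_equal(unname(dm$X[, "age"]), tab$age)
  expect_equal(dm$y, c(1, 0, 0, 1, 0))
  # source map is total over the encoded features and surjective onto sources
  expect_setequal(names(dm$source_map), colnames(dm$X))
  expect_setequal(unique(dm$source_map), c("color", "flag", "age"))
})

test_that("missing categorical values become an explicit level", {
  tab <- data.frame(v = c("a", NA, "b", NA), uses_iud = c(0, 1, 0, 1))
  dm <- one_hot(tab, "uses_iud", quiet = TRUE)
  expect_true("v=missing" %in% colnames(dm$X))
  expect_equal(unname(dm$X[, "v=missing"]), c(0, 1, 0, 1))
  expect_false(anyNA(dm$X))
  # missing continuous values are a hard error, not silent
  tab2 <- data.frame(z = c(1, NA, 3), uses_iud = c(0, 1, 0))
  expect_error(one_hot(tab2, "uses_iud", quiet = TRUE), "missing values")
})

test_that("constant columns are kept but flagged", {
  tab <- data.frame(k = rep("same", 4), x = c("a", "b", "a", "b"),
                    uses_iud = c(0, 1, 0, 1))
  expect_message(dm <- one_hot(tab, "uses_iud"), "constant")
  expect_true("k=same" %in% colnames(dm$X))
})

test_that("encoded column count equals the cardinality sum over the catalog", {
  set.seed(701)
  n <- 400
  cards <- sample(2:6, 30, replace = TRUE)
  tab <- as.data.frame(lapply(cards, function(k)
    sample(paste0("lv", seq_len(k)), n, replace = TRUE)))
  names(tab) <- paste0("v", seq_along(cards))
  tab$cont1 <- rnorm(n); tab$cont2 <- runif(n)
  tab$uses_iud <- rbinom(n, 1, 0.3)
  dm <- one_hot(tab, "uses_iud", quiet = TRUE)
  observed_cards <- vapply(paste0("v", seq_along(cards)), function(v)
    length(unique(tab[[v]])), 0L)
  expect_equal(ncol(dm$X), sum(observed_cards) + 2L)
  # row-sum-to-one for every encoded source variable
  for (v in paste0("v", seq_along(cards))) {
    block <- dm$X[, dm$source_map == v, drop = FALSE]
    expect_equal(unname(rowSums(block)), rep(1, n))
  }
})

test_that("catalogs and theme maps survive YAML and JSON round trips", {
  roles <- c(parity = "analysis", id = "irrelevant", uses_iud = "outcome")
  rules <- list(parity = list(
    list(label = "low", max = 2), list(label = "high", min = 3)))
  cat_ <- variable_catalog(roles, rules)
  for (ext in c(".yaml", ".json")) {
    p <- tempfile(fileext = ext)
    write_catalog(cat_, p)
    back <- read_catalog(p)
    expect_equal(back$roles[names(roles)], roles)
    expect_equal(length(back$rules$parity), 2L)
    unlink(p)
  }
  tm <- theme_map(list(a = c("t1", "t2"), b = "t1", c = character(0)))
  for (ext in c(".yaml", ".json")) {
    p <- tempfile(fileext = ext)
    write_theme_map(tm, p)
    back <- read_theme_map(p)
    expect_setequal(names(back), names(tm))
    expect_setequal(back$a, c("t1", "t2"))
    expect_length(back$c, 0L)
    unlink(p)
  }
})
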