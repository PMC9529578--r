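# Preprocessing: role-based variable screening, recategorization to
# literature-standard category schemes, and full one-hot encoding.
#
# The variable catalog declares, for every column of the raw table, its role:
#   analysis   - enters the model
#   outcome    - the binary outcome (exactly one)
#   irrelevant - identifiers and similar; carries no respondent information
#   redundant  - duplicate encoding of another retained variable
#   endogenous - essentially synonymous with the outcome
# plus optional recategorization rules (ordered label/predicate pairs).

CATALOG_ROLES <- c("analysis", "outcome", "irrelevant", "redundant", "endogenous")

#' Build a variable catalog
#'
#' @param roles named character vector mapping variable name to role, one of
#'   `analysis`, `outcome`, `irrelevant`, `redundant`, `endogenous`. Exactly
#'   one variable must have role `outcome`.
#' @param rules optional named list of recategorization rules. Each element is
#'   a list of rule specs `list(label =, values =)` (set membership) or
#'   `list(label =, min =, max =)` (inclusive numeric range; either bound may
#'   be omitted). Rules for a variable must be mutually exclusive; overlap is
#'   rejected at construction. Exhaustiveness over the observed values is
#'   checked when the rules are applied.
#' @return A `variable_catalog` object.
#' @export
variable_catalog <- function(roles, rules = NULL) {
  if (is.null(names(roles)) || any(names(roles) == ""))
    stop("roles must be a fully named character vector", call. = FALSE)
  bad <- setdiff(roles, CATALOG_ROLES)
  if (length(bad))
    stop("unknown roles: ", paste(unique(bad), collapse = ", "), call. = FALSE)
  if (sum(roles == "outcome") != 1L)
    stop("catalog must declare exactly one outcome variable", call. = FALSE)
  rules <- rules %||% list()
  unknown <- setdiff(names(rules), names(roles))
  if (length(unknown))
    stop("rules reference uncataloged variables: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (v in names(rules)) validate_rules(rules[[v]], v)
  structure(list(roles = roles, rules = rules), class = "variable_catalog")
}

# Mutual exclusivity is decidable at load time: explicit value sets must be
# pairwise disjoint, ranges pairwise non-overlapping, and listed values must
# not fall inside any range.
validate_rules <- function(rule_list, var) {
  if (!length(rule_list)) stop("empty rule list for ", var, call. = FALSE)
  labels <- vapply(rule_list, function(r) as.character(r$label %||% NA), "")
  if (anyNA(labels) || anyDuplicated(labels))
    stop("rules for ", var, " need unique labels", call. = FALSE)
  vals <- lapply(rule_list, function(r) r$values)
  rngs <- lapply(rule_list, function(r) {
    if (is.null(r$min) && is.null(r$max)) return(NULL)
    c(r$min %||% -Inf, r$max %||% Inf)
  })
  for (i in seq_along(rule_list)) {
    if (is.null(vals[[i]]) && is.null(rngs[[i]]))
      stop("rule '", labels[i], "' for ", var,
           " has neither values nor a range", call. = FALSE)
    for (j in seq_len(i - 1)) {
      if (!is.null(vals[[i]]) && !is.null(vals[[j]]) &&
          length(intersect(vals[[i]], vals[[j]])))
        stop("overlapping rules for ", var, ": '", labels[j], "' and '",
             labels[i], "' share values", call. = FALSE)
      if (!is.null(rngs[[i]]) && !is.null(rngs[[j]]) &&
          rngs[[i]][1] <= rngs[[j]][2] && rngs[[j]][1] <= rngs[[i]][2])
        stop("overlapping ranges for ", var, ": '", labels[j], "' and '",
             labels[i], "'", call. = FALSE)
      mixed <- function(vv, rr) {
        !is.null(vv) && !is.null(rr) && {
          nv <- suppressWarnings(as.numeric(vv))
          any(!is.na(nv) & nv >= rr[1] & nv <= rr[2])
        }
      }
      if (mixed(vals[[i]], rngs[[j]]) || mixed(vals[[j]], rngs[[i]]))
        stop("overlapping rules for ", var, ": '", labels[j], "' and '",
             labels[i], "' (value inside range)", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.variable_catalog <- function(x, ...) {
  cat(sprintf("Variable catalog: %d variables (%s); %d with recategorization rules\n",
              length(x$roles),
              paste(sprintf("%d %s", table(factor(x$roles, CATALOG_ROLES)),
                            CATALOG_ROLES)[table(factor(x$roles, CATALOG_ROLES)) > 0],
                    collapse = ", "),
              length(x$rules)))
  invisible(x)
}

#' Screen variables by catalog role
#'
#' Restricts the table to variables with role `analysis` or `outcome`,
#' logging every exclusion with its role. Every column of the table must
#' appear in the catalog.
#'
#' @param table a data.frame of raw survey responses.
#' @param catalog a [variable_catalog()].
#' @param quiet suppress per-exclusion log messages.
#' @return The table restricted to analysis + outcome columns.
#' @export
screen_variables <- function(table, catalog, quiet = FALSE) {
  stopifnot(is.data.frame(table), inherits(catalog, "variable_catalog"))
  uncat <- setdiff(names(table), names(catalog$roles))
  if (length(uncat))
    stop("uncataloged columns: ", paste(uncat, collapse = ", "), call. = FALSE)
  roles <- catalog$roles[names(table)]
  drop <- names(table)[!roles %in% c("analysis", "outcome")]
  if (!quiet) for (v in drop)
    message(sprintf("screening out '%s' (role: %s)", v, roles[[v]]))
  table[, roles %in% c("analysis", "outcome"), drop = FALSE]
}

#' Apply recategorization rules
#'
#' Replaces every ruled variable by its categorical recode; variables without
#' a rule pass through unchanged. Each observed non-missing value must match
#' exactly one rule (exhaustiveness is validated here; mutual exclusivity was
#' validated at catalog construction).
#'
#' @inheritParams screen_variables
#' @return The table with ruled columns recoded to factors whose levels follow
#'   the rule order.
#' @export
recategorize <- function(table, catalog) {
  stopifnot(is.data.frame(table), inherits(catalog, "variable_catalog"))
  for (v in intersect(names(catalog$rules), names(table))) {
    rl <- catalog$rules[[v]]
    x <- table[[v]]
    labels <- vapply(rl, function(r) as.character(r$label), "")
    # an already-recoded column (levels identical to the rule labels) passes
    # through, making the preprocessing chain idempotent
    if (is.factor(x) && identical(levels(x), labels)) next
    hit <- matrix(FALSE, length(x), length(rl))
    xn <- suppressWarnings(as.numeric(x))
    for (j in seq_along(rl)) {
      r <- rl[[j]]
      if (!is.null(r$values)) hit[, j] <- hit[, j] | (x %in% r$values)
      if (!is.null(r$min) || !is.null(r$max))
        hit[, j] <- hit[, j] |
          (!is.na(xn) & xn >= (r$min %||% -Inf) & xn <= (r$max %||% Inf))
    }
    nmatch <- rowSums(hit)
    obs <- !is.na(x)
    if (any(obs & nmatch == 0))
      stop("values of '", v, "' match no rule: ",
           paste(utils::head(unique(x[obs & nmatch == 0]), 10), collapse = ", "),
           call. = FALSE)
    if (any(nmatch > 1))
      stop("values of '", v, "' match multiple rules: ",
           paste(utils::head(unique(x[nmatch > 1]), 10), collapse = ", "),
           call. = FALSE)
    out <- rep(NA_character_, length(x))
    for (j in seq_along(rl)) out[hit[, j]] <- labels[j]
    table[[v]] <- factor(out, levels = labels)
  }
  table
}

#' One-hot encode a screened table into a design matrix
#'
#' Every categorical variable with k observed categories becomes k indicator
#' columns named `variable=level` (full encoding, no reference level dropped:
#' the selection stage reports individual category levels as features, which
#' requires every level to be named; the penalty resolves the induced
#' collinearity). Missing values become an explicit `missing` level.
#' Continuous (numeric) variables pass through on their raw scale;
#' standardization happens inside the fitting routines. Constant columns are
#' kept but flagged.
#'
#' @param table screened, recategorized data.frame including the outcome
#'   column.
#' @param outcome_name name of the binary 0/1 outcome column.
#' @param quiet suppress constant-column log messages.
#' @return A `design_matrix`: `X` (numeric matrix), `y` (0/1 vector),
#'   `feature_names`, `source_map` (named character vector, dummy name ->
#'   source variable) and `outcome_name`.
#' @export
one_hot <- function(table, outcome_name, quiet = FALSE) {
  stopifnot(is.data.frame(table))
  if (!outcome_name %in% names(table))
    stop("outcome column '", outcome_name, "' not found", call. = FALSE)
  y <- table[[outcome_name]]
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) y <- as.numeric(y)
  if (is.logical(y)) y <- as.numeric(y)
  y <- check_binary(y, outcome_name)

  vars <- setdiff(names(table), outcome_name)
  n <- nrow(table)
  blocks <- vector("list", length(vars))
  src <- character(0)
  for (i in seq_along(vars)) {
    v <- vars[i]
    x <- table[[v]]
    if (is.numeric(x)) {
      if (anyNA(x))
        stop("continuous variable '", v,
             "' has missing values; recategorize it or impute upstream",
             call. = FALSE)
      m <- matrix(x, ncol = 1, dimnames = list(NULL, v))
    } else {
      if (is.factor(x)) x <- as.character(x)
      x <- as.character(x)
      x[is.na(x)] <- "missing"
      levs <- sort(unique(x))
      m <- matrix(0, n, length(levs),
                  dimnames = list(NULL, paste0(v, "=", levs)))
      m[cbind(seq_len(n), match(x, levs))] <- 1
    }
    if (!quiet && length(unique(table[[v]])) == 1)
      message(sprintf("'%s' is constant; kept (penalization will handle it)", v))
    blocks[[i]] <- m
    src <- c(src, stats::setNames(rep(v, ncol(m)), colnames(m)))
  }
  X <- do.call(cbind, blocks)
  structure(list(X = X, y = y, feature_names = colnames(X), source_map = src,
                 outcome_name = outcome_name),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf(
    "Design matrix: %d respondents x %d features (%d source variables); outcome '%s', prevalence %.3f%%\n",
    nrow(x$X), ncol(x$X), length(unique(x$source_map)), x$outcome_name,
    100 * mean(x$y)))
  invisible(x)
}

#' Read/write catalogs and theme maps (YAML or JSON by extension)
#'
#' The catalog file is a mapping with keys `roles` (variable -> role) and
#' optional `rules`; the theme map file maps each variable to a (possibly
#' empty) list of theme labels.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @param catalog,tm objects to write.
#' @return Readers return the parsed object; writers invisibly return `path`.
#' @export
read_catalog <- function(path) {
  obj <- read_structured(path)
  rules <- lapply(obj$rules %||% list(), function(rl) {
    lapply(rl, function(r) r[!vapply(r, is.null, logical(1))])
  })
  variable_catalog(unlist(obj$roles), rules)
}

#' @rdname read_catalog
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "variable_catalog"))
  write_structured(list(roles = as.list(catalog$roles), rules = catalog$rules),
                   path)
}

#' @rdname read_catalog
#' @export
read_theme_map <- function(path) {
  obj <- read_structured(path)
  theme_map(lapply(obj, function(v) as.character(unlist(v))))
}

#' @rdname read_catalog
#' @export
write_theme_map <- function(tm, path) {
  stopifnot(inherits(tm, "theme_map"))
  write_structured(lapply(unclass(tm), as.list), path)
}

read_structured <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::read_json(path)
  else stop("expected a .yaml/.yml or .json file: ", path, call. = FALSE)
}

write_structured <- function(obj, path) {
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(obj, path)
  else if (grepl("\\.json$", path))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "list")
  else stop("expected a .yaml/.yml or .json file: ", path, call. = FALSE)
  invisible(path)
}
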