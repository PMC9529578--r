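# Internal helpers shared across modules.

#' Derive a component-specific seed from a run seed
#'
#' A single run seed drives every stochastic component (data generation, fold
#' assignment, train/test split, network initialization, permutations). Each
#' component derives its own stream seed by hashing the run seed together with
#' a short label, so components are reproducible independently of the order in
#' which they consume random numbers.
#'
#' @param seed integer run seed.
#' @param label character label naming the component (e.g. `"folds"`).
#' @return An integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647  # 2^31 - 1, prime
  h <- abs(as.numeric(seed)) %% m
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% m
  as.integer(h %% (m - 2) + 1)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Numerically stable log(1 + exp(x)).
softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

# Stable logistic function; never returns exactly 0 or 1.
sigmoid <- function(x) {
  p <- 1 / (1 + exp(-pmin(pmax(x, -700), 700)))
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps)
}

check_binary <- function(y, arg = "y") {
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop(sprintf("`%s` must be a binary 0/1 vector with no missing values", arg),
         call. = FALSE)
  invisible(as.numeric(y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
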