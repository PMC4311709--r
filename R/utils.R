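# internal helpers shared across modules

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' @noRd
check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (strict_lower && x <= lower)
    stopf("`%s` must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    stopf("`%s` must be >= %g (got %g)", name, lower, x)
  if (strict_upper && x >= upper)
    stopf("`%s` must be < %g (got %g)", name, upper, x)
  if (!strict_upper && x > upper)
    stopf("`%s` must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

#' @noRd
check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < lower)
    stopf("`%s` must be an integer >= %d", name, lower)
  as.integer(x)
}

# Evaluate `code` with the RNG seeded by `seed`, restoring the caller's
# RNG state afterwards so library calls do not perturb user scripts.
# seed = NULL leaves the global stream untouched (draws consume it).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  check_count(seed, "seed", lower = 0L)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic per-pair substream: adding pairs never perturbs earlier ones.
# Offsets kept well below .Machine$integer.max.
pair_seed <- function(seed, pair_index) {
  (as.integer(seed) + 7919L * as.integer(pair_index)) %% 2147483647L
}
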