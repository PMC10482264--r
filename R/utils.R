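# Internal helpers shared across modules.

stop_input <- function(...) {
  stop(structure(
    class = c("seqtrace_input_error", "error", "condition"),
    list(message = sprintf(...), call = sys.call(-1))
  ))
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_input("'%s' must be a single finite number", name)
  if (strict_lower && x <= lower)
    stop_input("'%s' must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    stop_input("'%s' must be >= %g (got %g)", name, lower, x)
  if (x > upper)
    stop_input("'%s' must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so package randomness never leaks into the session.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a reproducible child seed from a master seed, kept inside 32-bit range.
child_seed <- function(seed, i) {
  (as.double(seed) * 7919 + 104729 * as.double(i)) %% 2147483647
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level, default 0.95.
#' @return numeric vector `c(lower, upper)`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  assert_scalar_num(n, "n", lower = 1)
  assert_scalar_num(k, "k", lower = 0, upper = n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}
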