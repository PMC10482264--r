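#' Methods for fitted seqtrace models
#'
#' `retention_fit` and `trace_probe_fit` objects support the usual
#' modelling generics: `print`, `summary`, `coef`, `logLik`, `predict`,
#' `plot`, `simulate` and `residuals` (Pearson residuals on the
#' per-condition counts).
#'
#' @param object,x a fitted object from [fit_retention()] or
#'   [fit_trace_probes()].
#' @param ... unused.
#' @name seqtrace_fit-methods
NULL

#' @rdname seqtrace_fit-methods
#' @export
coef.seqtrace_fit <- function(object, ...) object$estimates

#' @rdname seqtrace_fit-methods
#' @export
logLik.seqtrace_fit <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$estimates),
            nobs = object$n_obs, class = "logLik")
}

#' @rdname seqtrace_fit-methods
#' @export
print.seqtrace_fit <- function(x, ...) {
  cat(sprintf("%s (n = %d)\n",
              switch(class(x)[1],
                     retention_fit = "Retention-curve fit",
                     trace_probe_fit = "Trace-model probe fit",
                     trace_probe_null = "Equal-probability null fit",
                     "Model fit"),
              x$n_obs))
  if (length(x$estimates) > 0) {
    cat("Estimates:\n")
    print(round(x$estimates, 4))
  }
  cat(sprintf("log-likelihood: %.3f  converged: %s\n",
              x$log_likelihood, x$converged))
  if (length(x$diagnostics) > 0)
    cat("diagnostics:", paste(x$diagnostics, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname seqtrace_fit-methods
#' @export
summary.seqtrace_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$se)) {
    cat("Standard errors:\n"); print(round(object$se, 4))
  }
  if (!is.null(object$profile_ci)) {
    cat("Profile confidence intervals:\n")
    print(round(object$profile_ci, 4))
  }
  if (!is.null(object$null_log_likelihood))
    cat(sprintf("deviance vs chance-level null: %.4f\n",
                2 * (object$log_likelihood - object$null_log_likelihood)))
  invisible(object)
}

#' @rdname seqtrace_fit-methods
#' @param newdata for `retention_fit`: numeric delays in seconds (defaults
#'   to the fitted delays); for `trace_probe_fit`: a data frame of
#'   `d_first`, `d_second` conditions.
#' @export
predict.retention_fit <- function(object, newdata = NULL, ...) {
  delays <- if (is.null(newdata)) object$data$delay_s else as.numeric(newdata)
  rp <- retention_params(object$estimates[["asymptote"]],
                         object$estimates[["decay_rate"]], object$chance)
  retention_curve(delays, rp)
}

#' @rdname seqtrace_fit-methods
#' @export
predict.trace_probe_fit <- function(object, newdata = NULL, ...) {
  conds <- if (is.null(newdata)) object$conditions else newdata
  pars <- c(as.list(object$estimates), object$fixed)
  tp <- trace_params(gain = pars$gain, decay = pars$decay, noise_sd = 0,
                     temperature = pars$temperature, lapse = pars$lapse)
  vapply(seq_len(nrow(conds)), function(i) {
    probe_prediction(conds$d_first[i], object$isi, conds$d_second[i],
                     params = tp)
  }, numeric(1))
}

#' @rdname seqtrace_fit-methods
#' @export
residuals.retention_fit <- function(object, ...) {
  p <- predict(object)
  with(object$data, (k - n * p) / sqrt(n * p * (1 - p)))
}

#' @rdname seqtrace_fit-methods
#' @export
residuals.trace_probe_fit <- function(object, ...) {
  p <- predict(object)
  with(object$data, (k_first - n * p) / sqrt(n * p * (1 - p)))
}

#' @rdname seqtrace_fit-methods
#' @param nsim number of simulated replicate datasets.
#' @param seed integer seed.
#' @export
simulate.retention_fit <- function(object, nsim = 1, seed = NULL, ...) {
  p <- predict(object)
  with_seed(seed, {
    replicate(nsim, stats::rbinom(length(p), object$data$n, p),
              simplify = FALSE)
  })
}

#' @rdname seqtrace_fit-methods
#' @export
plot.retention_fit <- function(x, ...) {
  d <- x$data
  ci <- t(mapply(wilson_ci, d$k, d$n))
  graphics::plot(d$delay_s, d$k / d$n, ylim = c(0, 1), pch = 19,
                 xlab = "Delay (s)", ylab = "Proportion correct",
                 main = "Retention curve", ...)
  graphics::arrows(d$delay_s, ci[, 1], d$delay_s, ci[, 2],
                   angle = 90, code = 3, length = 0.04)
  grid_d <- seq(0, max(d$delay_s) * 1.1, length.out = 100)
  graphics::lines(grid_d, predict(x, grid_d))
  graphics::abline(h = x$chance, lty = 3)
  invisible(x)
}

#' @rdname seqtrace_fit-methods
#' @export
plot.trace_probe_fit <- function(x, ...) {
  d <- x$data
  obs <- d$k_first / d$n
  pred <- predict(x)
  graphics::plot(seq_along(obs), obs, ylim = c(0, 1), pch = 19,
                 xlab = "Probe condition", ylab = "P(choose first sample)",
                 main = "Trace-model probe fit", xaxt = "n", ...)
  graphics::axis(1, at = seq_along(obs),
                 labels = sprintf("%g/%g", x$conditions$d_first,
                                  x$conditions$d_second))
  graphics::points(seq_along(pred), pred, pch = 4, col = 2)
  graphics::abline(h = 0.5, lty = 3)
  graphics::legend("topright", pch = c(19, 4), col = c(1, 2),
                   legend = c("observed", "fitted"), bty = "n")
  invisible(x)
}
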