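# Maximum-likelihood fitting of the retention curve and of the trace model
# to probe-choice counts. Both fitters return classed S3 objects with the
# usual modelling methods (print, summary, coef, predict, plot, logLik,
# simulate, residuals).

clamp_p <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

binom_ll <- function(k, n, p) sum(stats::dbinom(k, n, clamp_p(p), log = TRUE))

multi_start_optim <- function(starts, nll, lower, upper, tol = 1e-8) {
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[s, ], nll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = tol / .Machine$double.eps,
                                  maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  best
}

new_fit <- function(subclass, estimates, log_likelihood, converged, n_obs,
                    diagnostics = character(), ...) {
  structure(
    c(list(estimates = estimates, log_likelihood = log_likelihood,
           converged = converged, n_obs = n_obs,
           diagnostics = diagnostics), list(...)),
    class = c(subclass, "seqtrace_fit")
  )
}

#' Fit the exponential retention curve by maximum likelihood
#'
#' Fits accuracy-vs-delay data from a delayed matching-to-sample task with
#' independent Binomial likelihoods
#' \eqn{k_d \sim \mathrm{Bin}(n_d,\; c + (1-c)\,a\,e^{-\lambda_r d})},
#' estimating the amplitude `asymptote` (a, in \[0, 1\]) and forgetting
#' rate `decay_rate` (\eqn{\lambda_r \ge 0}) with the chance level `c`
#' fixed. Bounded quasi-Newton (L-BFGS-B) from 8 fixed multi-starts;
#' standard errors from the numerical Hessian where available. When the
#' data carry no above-chance signal the fit degenerates to a = 0 with
#' `decay_rate` unidentified; this is reported via the `flat_likelihood`
#' diagnostic rather than an error.
#'
#' @param delays distinct retention delays in seconds (>= 2 values).
#' @param k correct counts per delay.
#' @param n trial counts per delay.
#' @param chance fixed guessing accuracy (0.5 for two options).
#' @return a `retention_fit` object; see [seqtrace_fit-methods].
#' @examples
#' rp <- retention_params(0.7, 0.25)
#' d <- c(0, 2, 5, 10); n <- rep(500, 4)
#' k <- c(424, 330, 301, 260)
#' fit_retention(d, k, n)
#' @export
fit_retention <- function(delays, k, n, chance = 0.5) {
  if (length(unique(delays)) < 2L)
    stop_input(
      "at least 2 distinct delays are required; the curve is unidentifiable")
  if (length(k) != length(delays) || length(n) != length(delays))
    stop_input("delays, k and n must have equal length")
  if (any(k < 0) || any(n <= 0) || any(k > n))
    stop_input("need 0 <= k <= n with n > 0 at every delay")
  if (any(delays < 0)) stop_input("delays must be non-negative")
  assert_scalar_num(chance, "chance", lower = 0, upper = 1)

  nll <- function(par) {
    p <- chance + (1 - chance) * par[1] * exp(-par[2] * delays)
    -binom_ll(k, n, p)
  }
  starts <- as.matrix(expand.grid(a = c(0.2, 0.5, 0.8, 0.95),
                                  lambda = c(0.05, 0.5)))
  best <- multi_start_optim(starts, nll, lower = c(0, 0), upper = c(1, 50))
  est <- c(asymptote = unname(best$par[1]), decay_rate = unname(best$par[2]))
  ll <- -best$value
  ll_null <- binom_ll(k, n, rep(chance, length(k)))
  diagnostics <- character()
  if (2 * (ll - ll_null) < 1e-6) {
    diagnostics <- c(diagnostics, "flat_likelihood")
    if (est[["asymptote"]] < 1e-6)
      diagnostics <- c(diagnostics, "decay_rate_unidentified")
  }
  se <- tryCatch({
    H <- stats::optimHess(best$par, nll)
    s <- sqrt(diag(solve(H)))
    names(s) <- names(est)
    s
  }, error = function(e) NULL)
  new_fit("retention_fit", est, ll, converged = best$convergence == 0,
          n_obs = sum(n), diagnostics = diagnostics, se = se,
          chance = chance,
          data = data.frame(delay_s = delays, k = k, n = n),
          null_log_likelihood = ll_null)
}

# Closed form of probe_prediction() on the default saturating/exponential
# laws, vectorised over conditions (agrees with probe_prediction to
# rounding; covered by tests). Used for speed inside the optimizer.
probe_pred_vec <- function(d1, d2, isi, gain, decay, temperature, lapse) {
  i1 <- (1 - exp(-gain * d1)) * exp(-decay * (isi + d2))
  i2 <- 1 - exp(-gain * d2)
  p <- stats::plogis(temperature * (i1 - i2))
  (1 - lapse) * p + lapse / 2
}

# Negative log-likelihood of the probe counts under the trace model.
probe_nll_factory <- function(k_first, n_row, conditions, isi, fixed) {
  function(par) {
    pars <- c(as.list(par), fixed)
    p <- probe_pred_vec(conditions$d_first, conditions$d_second, isi,
                        pars$gain, pars$decay, pars$temperature, pars$lapse)
    -binom_ll(k_first, n_row, p)
  }
}

#' Fit the trace model to probe-choice counts
#'
#' Maximum-likelihood fit of the trace model to a 6 x 2 table of probe
#' choices (first-sample vs second-sample stimulus per duration condition):
#' \eqn{k_i \sim \mathrm{Bin}(n_i, \pi_i)} with
#' \eqn{\pi_i = } [probe_prediction()] at condition \eqn{i}. With only six
#' conditions and small counts, gain, decay and temperature are jointly
#' weakly identified, so by default the encoding gain is pinned at 1 and
#' the lapse at 0, and (decay, temperature) are estimated; pins can be
#' changed via `fixed`. Profile-likelihood 95% confidence intervals are
#' reported for the free parameters. When the fitted model improves on the
#' equal-probability null by less than 1e-6 in deviance the
#' `flat_likelihood` diagnostic is set — the degenerate outcome in which
#' the counts carry no duration signal.
#'
#' @param table matrix of counts with columns (chose first, chose second),
#'   rows aligned with `conditions` (e.g. `probe_tables(log)$table`).
#' @param conditions data frame of duration conditions
#'   (default [probe_conditions()]).
#' @param isi inter-stimulus interval in seconds (default 0.3).
#' @param fixed named list of pinned parameters; default
#'   `list(gain = 1, lapse = 0)`.
#' @param profile compute profile confidence intervals (default TRUE).
#' @param conf confidence level for the profile intervals.
#' @return a `trace_probe_fit` object; see [seqtrace_fit-methods].
#' @export
fit_trace_probes <- function(table, conditions = probe_conditions(),
                             isi = 0.3, fixed = list(gain = 1, lapse = 0),
                             profile = TRUE, conf = 0.95) {
  O <- unclass(as.matrix(table))
  if (nrow(O) != nrow(conditions))
    stop_input("table has %d rows but %d conditions were given",
               nrow(O), nrow(conditions))
  if (ncol(O) != 2L) stop_input("table must have exactly 2 columns")
  k_first <- O[, 1]; n_row <- rowSums(O)
  if (any(n_row == 0)) stop_input("every condition needs at least one choice")

  all_pars <- c(gain = 1, decay = 0.5, temperature = 3, lapse = 0)
  bounds <- list(gain = c(1e-3, 20), decay = c(0, 10),
                 temperature = c(0, 50), lapse = c(0, 0.5))
  free <- setdiff(names(all_pars), names(fixed))
  if (length(free) == 0L) stop_input("at least one parameter must be free")
  nll <- probe_nll_factory(k_first, n_row, conditions, isi, fixed)

  start_grid <- list(gain = c(0.5, 2), decay = c(0.1, 1),
                     temperature = c(1, 8), lapse = c(0.01, 0.2))
  starts <- as.matrix(expand.grid(start_grid[free]))
  if (nrow(starts) > 8L) starts <- starts[seq_len(8L), , drop = FALSE]
  lower <- vapply(free, function(p) bounds[[p]][1], numeric(1))
  upper <- vapply(free, function(p) bounds[[p]][2], numeric(1))
  best <- multi_start_optim(starts, nll, lower, upper)
  est <- best$par; names(est) <- free
  ll <- -best$value
  ll_null <- binom_ll(k_first, n_row, rep(0.5, length(k_first)))

  diagnostics <- character()
  if (2 * (ll - ll_null) < 1e-6)
    diagnostics <- c(diagnostics, "flat_likelihood")

  ci <- NULL
  if (profile)
    ci <- profile_cis(nll, est, lower, upper, -ll, conf)

  new_fit("trace_probe_fit", est, ll, converged = best$convergence == 0,
          n_obs = sum(n_row), diagnostics = diagnostics,
          profile_ci = ci, fixed = fixed, conditions = conditions,
          isi = isi, data = data.frame(k_first = k_first, n = n_row),
          null_log_likelihood = ll_null)
}

# Profile-likelihood CIs: for each free parameter, re-optimize the others at
# fixed values and find where the profiled deviance crosses the chi-squared
# cutoff. Endpoints at the box bounds are reported as the bounds.
profile_cis <- function(nll, est, lower, upper, nll_min, conf = 0.95) {
  cutoff <- stats::qchisq(conf, df = 1) / 2
  free <- names(est)
  prof_nll <- function(j, value) {
    others <- setdiff(seq_along(est), j)
    if (length(others) == 0L) {
      par <- value; names(par) <- free[j]
      return(nll(par))
    }
    f <- function(po) {
      par <- numeric(length(est)); names(par) <- free
      par[j] <- value; par[others] <- po
      nll(par)
    }
    if (length(others) == 1L) {
      stats::optimize(f, lower = lower[others], upper = upper[others])$objective
    } else {
      stats::optim(est[others], f, method = "L-BFGS-B",
                   lower = lower[others], upper = upper[others])$value
    }
  }
  ci <- matrix(NA_real_, nrow = length(est), ncol = 2,
               dimnames = list(free, c("lower", "upper")))
  for (j in seq_along(est)) {
    g <- function(v) prof_nll(j, v) - nll_min - cutoff
    # lower endpoint
    lo <- lower[j]
    ci[j, 1] <- if (g(lo) <= 0) lo else
      tryCatch(stats::uniroot(g, c(lo, est[j]), tol = 1e-6)$root,
               error = function(e) lo)
    hi <- upper[j]
    ci[j, 2] <- if (g(hi) <= 0) hi else
      tryCatch(stats::uniroot(g, c(est[j], hi), tol = 1e-6)$root,
               error = function(e) hi)
  }
  ci
}

#' Likelihood-ratio test between nested fits
#'
#' @param fit_full,fit_null fitted objects (any `seqtrace_fit`), the null
#'   nested in the full.
#' @param df difference in free parameters (> 0).
#' @return a `test_result` with the deviance, df and chi-squared p-value.
#' @export
lr_test <- function(fit_full, fit_null, df) {
  assert_scalar_num(df, "df", lower = 1)
  ll_full <- if (inherits(fit_full, "seqtrace_fit"))
    fit_full$log_likelihood else as.numeric(fit_full)
  ll_null <- if (inherits(fit_null, "seqtrace_fit"))
    fit_null$log_likelihood else as.numeric(fit_null)
  dev <- 2 * (ll_full - ll_null)
  if (dev < -1e-8)
    stop("negative deviance (", format(dev), "): the 'full' model fits ",
         "worse than the null; optimization failure")
  dev <- max(dev, 0)
  new_test_result(statistic = dev, df = as.integer(df),
                  p_value = stats::pchisq(dev, df, lower.tail = FALSE),
                  method = "Likelihood-ratio test",
                  n = if (inherits(fit_full, "seqtrace_fit"))
                    fit_full$n_obs else NA_integer_)
}

#' Reference fits for the probe table
#'
#' Null and saturated models against which the trace model (or the choice
#' data themselves) can be assessed by likelihood ratio:
#' \describe{
#'   \item{`"chance"`}{every condition chooses the first sample with
#'     probability 0.5; zero free parameters.}
#'   \item{`"equal_choice"`}{one common first-choice probability shared by
#'     all conditions, estimated from the data (its ML estimate is the
#'     pooled proportion); one free parameter. This is the "same choice
#'     distribution after every probe type" hypothesis: comparing the
#'     saturated model against it with df = rows - 1 is the
#'     likelihood-ratio analogue of the Pearson homogeneity test, and
#'     comparing the trace fit against it asks whether stimulus durations
#'     modulate choice beyond a constant (e.g. recency) preference.}
#'   \item{`"saturated"`}{one free probability per condition.}
#' }
#'
#' @param table counts matrix as in [fit_trace_probes()].
#' @param null which reference model (default `"chance"`).
#' @return a `trace_probe_null` fit object.
#' @seealso [lr_test()]
#' @export
fit_probe_null <- function(table,
                           null = c("chance", "equal_choice", "saturated")) {
  null <- match.arg(null)
  O <- unclass(as.matrix(table))
  k_first <- O[, 1]; n_row <- rowSums(O)
  p <- switch(null,
    chance = rep(0.5, length(k_first)),
    equal_choice = rep(sum(k_first) / sum(n_row), length(k_first)),
    saturated = k_first / n_row)
  est <- switch(null,
    chance = numeric(0),
    equal_choice = c(p_first = sum(k_first) / sum(n_row)),
    saturated = stats::setNames(p, rownames(O)))
  new_fit("trace_probe_null", estimates = est,
          log_likelihood = binom_ll(k_first, n_row, p),
          converged = TRUE, n_obs = sum(n_row), null = null)
}
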