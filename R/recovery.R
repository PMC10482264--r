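#' Parameter-recovery study
#'
#' Simulate-then-fit validation of the fitting routines: data are generated
#' at known parameters under a given design, refit, and the per-parameter
#' bias, RMSE and confidence-interval coverage are reported. Deterministic
#' given the seed.
#'
#' Two designs are supported, selected by `design$model`:
#' \describe{
#'   \item{`"retention"`}{`design` carries `delays`, `n_per_delay`,
#'     `chance`; `truth` is a [retention_params()] object (or list with
#'     `asymptote`, `decay_rate`). Coverage uses Wald intervals from the
#'     numerical Hessian.}
#'   \item{`"trace"`}{`design` carries `conditions` (data frame of
#'     `d_first`, `d_second`), `isi`, `reps_per_condition`; `truth` is a
#'     [trace_params()] object. The counts are Binomial draws from
#'     [probe_prediction()]; gain and lapse are pinned at their true values
#'     and (decay, temperature) are fitted. Coverage uses the profile
#'     intervals.}
#' }
#'
#' @param truth generating parameters (see above).
#' @param design list describing the design (see above).
#' @param reps number of simulation replicates (>= 2).
#' @param seed integer seed.
#' @param conf nominal confidence level.
#' @return a `recovery_study` object: list with `per_parameter` (data frame
#'   of truth, mean estimate, bias, rmse, coverage) and `estimates` (reps x
#'   parameters matrix).
#' @examples
#' recovery_study(retention_params(0.7, 0.25),
#'                list(model = "retention", delays = c(0, 2, 5, 10),
#'                     n_per_delay = 200),
#'                reps = 5, seed = 1)
#' @export
recovery_study <- function(truth, design, reps, seed, conf = 0.95) {
  assert_scalar_num(reps, "reps", lower = 2)
  reps <- as.integer(reps)
  model <- design$model
  if (is.null(model) || !model %in% c("retention", "trace"))
    stop_input("design$model must be 'retention' or 'trace'")

  if (model == "retention") {
    delays <- design$delays
    n_d <- rep(design$n_per_delay, length.out = length(delays))
    chance <- if (is.null(design$chance)) 0.5 else design$chance
    rp <- if (inherits(truth, "retention_params")) truth
          else retention_params(truth$asymptote, truth$decay_rate, chance)
    p_true <- retention_curve(delays, rp)
    true_vec <- c(asymptote = rp$asymptote, decay_rate = rp$decay_rate)
    one_rep <- function() {
      k <- stats::rbinom(length(delays), n_d, p_true)
      fit <- fit_retention(delays, k, n_d, chance = chance)
      z <- stats::qnorm(1 - (1 - conf) / 2)
      covered <- if (is.null(fit$se)) rep(NA, 2) else
        abs(coef(fit) - true_vec) <= z * fit$se
      list(est = coef(fit), covered = covered)
    }
  } else {
    tp <- truth
    stopifnot(inherits(tp, "trace_params"))
    conds <- if (is.null(design$conditions)) probe_conditions()
             else design$conditions
    isi <- if (is.null(design$isi)) 0.3 else design$isi
    n_row <- rep(design$reps_per_condition, nrow(conds))
    p_true <- vapply(seq_len(nrow(conds)), function(i) {
      probe_prediction(conds$d_first[i], isi, conds$d_second[i], params = tp)
    }, numeric(1))
    true_vec <- c(decay = tp$decay, temperature = tp$temperature)
    one_rep <- function() {
      k <- stats::rbinom(nrow(conds), n_row, p_true)
      tab <- cbind(k, n_row - k)
      fit <- fit_trace_probes(tab, conds, isi,
                              fixed = list(gain = tp$gain, lapse = tp$lapse),
                              profile = TRUE, conf = conf)
      covered <- true_vec >= fit$profile_ci[names(true_vec), "lower"] &
        true_vec <= fit$profile_ci[names(true_vec), "upper"]
      list(est = coef(fit)[names(true_vec)], covered = covered)
    }
  }

  runs <- with_seed(seed, replicate(reps, one_rep(), simplify = FALSE))
  est <- do.call(rbind, lapply(runs, `[[`, "est"))
  cov <- do.call(rbind, lapply(runs, `[[`, "covered"))
  per_parameter <- data.frame(
    parameter = names(true_vec),
    truth = unname(true_vec),
    mean_estimate = colMeans(est),
    bias = colMeans(est) - unname(true_vec),
    rmse = sqrt(colMeans(sweep(est, 2, true_vec)^2)),
    coverage = colMeans(cov),
    row.names = NULL
  )
  structure(list(per_parameter = per_parameter, estimates = est,
                 covered = cov, reps = reps, model = model, conf = conf),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf("Parameter recovery (%s model, %d replicates, %g%% CIs):\n",
              x$model, x$reps, 100 * x$conf))
  df <- x$per_parameter
  df[, -1] <- round(df[, -1], 4)
  print(df, row.names = FALSE)
  invisible(x)
}
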