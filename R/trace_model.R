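#' Trace-model parameters
#'
#' Bundles the parameters of the memory-trace model: how fast a stimulus
#' presentation builds trace intensity, how fast the trace fades afterwards,
#' and how noisy, sharp and lapse-prone trace-based choices are.
#'
#' @param gain encoding rate \eqn{g} (per second, > 0): with the default
#'   saturating law a presentation of duration \eqn{d} leaves an initial
#'   intensity \eqn{1 - e^{-g d}}.
#' @param decay decay rate \eqn{\lambda} (per second, >= 0): intensity is
#'   multiplied by \eqn{e^{-\lambda t}} over a retention interval of \eqn{t}
#'   seconds. `decay = 0` means no forgetting.
#' @param noise_sd standard deviation \eqn{\sigma} of the zero-mean Gaussian
#'   perturbation applied to intensities at decision time (>= 0).
#' @param temperature softmax inverse temperature \eqn{\beta} (>= 0) used by
#'   the deterministic (noise-free) choice rule.
#' @param lapse lapse probability \eqn{\epsilon} in \[0, 1\]: with this
#'   probability the response is uniform over the displayed options,
#'   regardless of the traces.
#' @param encoding `"saturating"` (default) for \eqn{1 - e^{-g d}} or
#'   `"linear"` for \eqn{g d}.
#' @return an object of class `trace_params`.
#' @seealso [encode_intensity()], [trace_state()], [choice_probabilities()],
#'   [probe_prediction()]
#' @examples
#' trace_params(gain = 1, decay = 0.5, noise_sd = 0.3)
#' @export
trace_params <- function(gain = 1, decay = 0.5, noise_sd = 0.3,
                         temperature = 3, lapse = 0.02,
                         encoding = c("saturating", "linear")) {
  assert_scalar_num(gain, "gain", lower = 0, strict_lower = TRUE)
  assert_scalar_num(decay, "decay", lower = 0)
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  assert_scalar_num(temperature, "temperature", lower = 0)
  assert_scalar_num(lapse, "lapse", lower = 0, upper = 1)
  encoding <- match.arg(encoding)
  structure(
    list(gain = gain, decay = decay, noise_sd = noise_sd,
         temperature = temperature, lapse = lapse, encoding = encoding),
    class = "trace_params"
  )
}

#' @export
print.trace_params <- function(x, ...) {
  cat("Trace-model parameters:\n")
  cat(sprintf("  gain        g      = %g /s (%s encoding)\n", x$gain, x$encoding))
  cat(sprintf("  decay       lambda = %g /s\n", x$decay))
  cat(sprintf("  noise s.d.  sigma  = %g\n", x$noise_sd))
  cat(sprintf("  temperature beta   = %g\n", x$temperature))
  cat(sprintf("  lapse       eps    = %g\n", x$lapse))
  invisible(x)
}

#' Retention-curve parameters
#'
#' Parameters of the exponential retention curve used to summarise delayed
#' matching-to-sample performance: accuracy starts at
#' `chance + (1 - chance) * asymptote` at zero delay and relaxes towards
#' `chance` as the delay grows.
#'
#' @param asymptote amplitude \eqn{a} in \[0, 1\] on the above-chance scale.
#' @param decay_rate forgetting rate \eqn{\lambda_r} (per second, >= 0).
#' @param chance guessing accuracy \eqn{c} in (0, 1); 0.5 for two options.
#' @return an object of class `retention_params`.
#' @seealso [retention_curve()], [fit_retention()]
#' @export
retention_params <- function(asymptote = 0.8, decay_rate = 0.2, chance = 0.5) {
  assert_scalar_num(asymptote, "asymptote", lower = 0, upper = 1)
  assert_scalar_num(decay_rate, "decay_rate", lower = 0)
  if (!is.numeric(chance) || length(chance) != 1L || chance <= 0 || chance >= 1)
    stop_input("'chance' must lie strictly between 0 and 1")
  structure(
    list(asymptote = asymptote, decay_rate = decay_rate, chance = chance),
    class = "retention_params"
  )
}

#' @export
print.retention_params <- function(x, ...) {
  cat(sprintf(
    "Retention curve: p(delay) = %g + %g * %g * exp(-%g * delay)\n",
    x$chance, 1 - x$chance, x$asymptote, x$decay_rate))
  invisible(x)
}

#' Timed stimulus events
#'
#' Builds a set of timed stimulus presentations (the sample sequence of a
#' trial). Events must be non-overlapping, time-ordered and strictly
#' positive in duration.
#'
#' @param stimulus_id character vector of stimulus identities.
#' @param onset,offset numeric vectors of onset/offset times in seconds.
#' @return a data frame of class `stimulus_events` with columns
#'   `stimulus_id`, `onset`, `offset`.
#' @examples
#' stimulus_events(c("A", "B"), onset = c(0, 1.3), offset = c(1, 2.3))
#' @export
stimulus_events <- function(stimulus_id, onset, offset) {
  n <- length(stimulus_id)
  if (length(onset) != n || length(offset) != n)
    stop_input("stimulus_id, onset and offset must have equal length")
  if (n == 0L) stop_input("at least one event is required")
  if (any(!is.finite(onset)) || any(!is.finite(offset)))
    stop_input("onsets and offsets must be finite")
  if (any(onset < 0)) stop_input("onsets must be >= 0")
  if (any(offset <= onset)) stop_input("every event needs offset > onset")
  if (is.unsorted(onset, strictly = FALSE))
    stop_input("events must be ordered by onset")
  if (n > 1L && any(onset[-1L] < offset[-n]))
    stop_input("events must not overlap in time")
  structure(
    data.frame(stimulus_id = as.character(stimulus_id),
               onset = as.numeric(onset), offset = as.numeric(offset),
               stringsAsFactors = FALSE),
    class = c("stimulus_events", "data.frame")
  )
}

#' Encoding intensity of a single presentation
#'
#' Initial trace intensity laid down by presenting a stimulus for `duration`
#' seconds. The default saturating law \eqn{1 - e^{-g d}} is strictly
#' increasing in duration and bounded by 1; the linear alternative
#' \eqn{g d} is unbounded.
#'
#' @param duration presentation duration in seconds (> 0); vectorised.
#' @param params a [trace_params()] object.
#' @return non-negative intensity, same length as `duration`.
#' @examples
#' encode_intensity(1, trace_params(gain = 1))   # 1 - exp(-1) ~ 0.632
#' @export
encode_intensity <- function(duration, params) {
  stopifnot(inherits(params, "trace_params"))
  if (!is.numeric(duration) || length(duration) == 0L ||
      any(!is.finite(duration)) || any(duration <= 0))
    stop_input("'duration' must be strictly positive")
  if (params$encoding == "linear") params$gain * duration
  else 1 - exp(-params$gain * duration)
}

#' Trace intensities at a query time
#'
#' Computes the state of the unstructured trace memory at time `t`: for each
#' stimulus, the sum over its presentations of the encoding intensity decayed
#' exponentially over the interval since that presentation's offset.
#' Intensities are additive over repeated presentations; stimulus order is
#' not represented — only these intensities are.
#'
#' @param events a [stimulus_events()] object (or data frame with the same
#'   columns).
#' @param t query time in seconds; must be at or after the last offset.
#' @param params a [trace_params()] object.
#' @return an object of class `trace_state`: a list with `intensities`
#'   (named numeric vector) and `query_time`.
#' @examples
#' ev <- stimulus_events(c("A", "B"), c(0, 1.3), c(1, 2.3))
#' trace_state(ev, t = 2.3, params = trace_params(gain = 1, decay = 0.5))
#' @export
trace_state <- function(events, t, params) {
  stopifnot(inherits(params, "trace_params"))
  if (!is.data.frame(events) ||
      !all(c("stimulus_id", "onset", "offset") %in% names(events)))
    stop_input("'events' must have columns stimulus_id, onset, offset")
  assert_scalar_num(t, "t")
  if (t < max(events$offset))
    stop_input("query time t (%g) precedes the last event offset (%g)",
               t, max(events$offset))
  enc <- encode_intensity(events$offset - events$onset, params)
  contrib <- enc * exp(-params$decay * (t - events$offset))
  intensities <- vapply(split(contrib, events$stimulus_id), sum, numeric(1))
  structure(list(intensities = intensities, query_time = t),
            class = "trace_state")
}

#' @export
print.trace_state <- function(x, ...) {
  cat(sprintf("Trace state at t = %g s:\n", x$query_time))
  print(round(x$intensities, 5))
  invisible(x)
}

# Intensity lookup that returns exactly 0 for never-presented stimuli.
state_intensity <- function(state, ids) {
  out <- state$intensities[ids]
  out[is.na(out)] <- 0
  names(out) <- ids
  out
}

# P(option i attains the maximum after adding N(0, sd) noise to each
# intensity), by Gauss-Hermite quadrature over the winning option's noise.
gaussian_max_probs <- function(intensity, sd, n_nodes = 61) {
  k <- length(intensity)
  if (sd <= 0) {
    top <- intensity == max(intensity)
    return(top / sum(top))
  }
  # Hermite nodes/weights for E[f(Z)], Z ~ N(0,1), via eigen-decomposition
  # of the Jacobi matrix (Golub-Welsch).
  i <- seq_len(n_nodes - 1)
  J <- matrix(0, n_nodes, n_nodes)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  eig <- eigen(J, symmetric = TRUE)
  nodes <- eig$values * sqrt(2)          # z-scale nodes
  weights <- eig$vectors[1, ]^2          # sum to 1
  probs <- vapply(seq_len(k), function(j) {
    others <- intensity[-j]
    vals <- vapply(nodes, function(z) {
      prod(stats::pnorm((intensity[j] + sd * z - others) / sd))
    }, numeric(1))
    sum(weights * vals)
  }, numeric(1))
  probs / sum(probs)
}

#' Choice probabilities from a trace state
#'
#' Maps trace intensities of the displayed options to response
#' probabilities. Two rules are available:
#' \describe{
#'   \item{`"softmax"`}{the Luce/softmax rule over
#'     \eqn{\beta \cdot} intensity, mixed with the lapse rate
#'     \eqn{\epsilon} towards the uniform distribution.}
#'   \item{`"noisy_max"`}{each intensity is perturbed by independent
#'     zero-mean Gaussian noise of s.d. \eqn{\sigma} and the maximum is
#'     chosen; the resulting win probabilities are computed exactly by
#'     one-dimensional Gauss-Hermite quadrature, then mixed with the lapse.}
#' }
#' Both rules return a deterministic probability vector; sampling of an
#' actual response happens in the agents.
#'
#' @param state a [trace_state()] object.
#' @param options character vector of displayed stimulus ids (non-empty,
#'   unique). Options never presented have intensity exactly 0.
#' @param params a [trace_params()] object.
#' @param rule `"softmax"` (default) or `"noisy_max"`.
#' @return named probability vector over `options`, summing to 1.
#' @examples
#' ev <- stimulus_events(c("A", "B"), c(0, 1.3), c(1, 2.3))
#' st <- trace_state(ev, 2.3, trace_params(decay = 0.5))
#' choice_probabilities(st, c("A", "B", "C", "D"), trace_params(decay = 0.5))
#' @export
choice_probabilities <- function(state, options, params,
                                 rule = c("softmax", "noisy_max")) {
  stopifnot(inherits(state, "trace_state"), inherits(params, "trace_params"))
  rule <- match.arg(rule)
  if (length(options) == 0L) stop_input("'options' must be non-empty")
  if (anyDuplicated(options)) stop_input("'options' must be unique")
  intensity <- state_intensity(state, options)
  k <- length(options)
  if (rule == "softmax") {
    z <- params$temperature * intensity
    z <- z - max(z)                      # guard overflow
    p <- exp(z) / sum(exp(z))
  } else {
    p <- gaussian_max_probs(intensity, params$noise_sd)
  }
  p <- (1 - params$lapse) * p + params$lapse / k
  names(p) <- options
  p
}

#' Trace-model prediction for a two-stimulus probe trial
#'
#' For a probe sequence (first stimulus shown `d_first` s, gap of `isi` s,
#' second stimulus shown `d_second` s, then a `retention_gap` before the
#' options appear), returns the probability of choosing the *first* sample
#' stimulus, conditional on one of the two sample stimuli being chosen.
#' Non-matching options carry intensity 0 and drop out of the conditional
#' two-option comparison, which uses the softmax rule with the model's
#' temperature and lapse.
#'
#' A longer first stimulus leaves a stronger (decayed) trace, so this
#' probability is non-decreasing in `d_first`; with positive decay and equal
#' durations recency makes it < 0.5.
#'
#' @param d_first,d_second durations of the two sample stimuli in seconds
#'   (> 0).
#' @param isi inter-stimulus interval in seconds (>= 0).
#' @param retention_gap delay between second-stimulus offset and options
#'   onset, in seconds (>= 0, default 0).
#' @param params a [trace_params()] object.
#' @return probability of choosing the first-sample stimulus.
#' @examples
#' probe_prediction(1, 0.3, 4.5, params = trace_params(decay = 0.7))
#' @export
probe_prediction <- function(d_first, isi, d_second, retention_gap = 0,
                             params) {
  stopifnot(inherits(params, "trace_params"))
  assert_scalar_num(d_first, "d_first", lower = 0, strict_lower = TRUE)
  assert_scalar_num(d_second, "d_second", lower = 0, strict_lower = TRUE)
  assert_scalar_num(isi, "isi", lower = 0)
  assert_scalar_num(retention_gap, "retention_gap", lower = 0)
  ev <- stimulus_events(
    c(".first", ".second"),
    onset = c(0, d_first + isi),
    offset = c(d_first, d_first + isi + d_second)
  )
  st <- trace_state(ev, t = d_first + isi + d_second + retention_gap, params)
  p <- choice_probabilities(st, c(".first", ".second"), params,
                            rule = "softmax")
  unname(p[1])
}

#' Exponential retention curve
#'
#' Predicted proportion correct in a matching-to-sample task after a given
#' retention delay: `chance + (1 - chance) * asymptote * exp(-decay_rate *
#' delay)`. The value always lies in `[chance, 1]`.
#'
#' @param delay retention delay in seconds (>= 0); vectorised.
#' @param rp a [retention_params()] object.
#' @return predicted proportion correct.
#' @examples
#' retention_curve(c(0, 2, 5, 10), retention_params(0.8, 0.2, 0.5))
#' @export
retention_curve <- function(delay, rp) {
  stopifnot(inherits(rp, "retention_params"))
  if (!is.numeric(delay) || any(!is.finite(delay)) || any(delay < 0))
    stop_input("'delay' must be non-negative")
  rp$chance + (1 - rp$chance) * rp$asymptote * exp(-rp$decay_rate * delay)
}

#' Serialize model parameters to a flat JSON config
#'
#' @param x a [trace_params()] or [retention_params()] object.
#' @param path optional file path; if `NULL`, the JSON string is returned.
#' @return the JSON string, invisibly if written to a file.
#' @export
params_to_json <- function(x, path = NULL) {
  if (inherits(x, "trace_params")) {
    obj <- list(gain = x$gain, decay = x$decay, noise_sd = x$noise_sd,
                temperature = x$temperature, lapse = x$lapse,
                encoding = x$encoding)
  } else if (inherits(x, "retention_params")) {
    obj <- list(asymptote = x$asymptote, decay_rate = x$decay_rate,
                chance = x$chance)
  } else stop_input("unsupported parameter object")
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}

#' Read model parameters from a flat JSON config
#'
#' Recognises trace-model configs (keys `gain`, `decay`, `noise_sd`,
#' `temperature`, `lapse`) and retention configs (keys `asymptote`,
#' `decay_rate`, `chance`).
#'
#' @param path a file path or a JSON string.
#' @return a [trace_params()] or [retention_params()] object.
#' @export
params_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (all(c("gain", "decay") %in% names(obj))) {
    trace_params(
      gain = obj$gain, decay = obj$decay,
      noise_sd = if (is.null(obj$noise_sd)) 0.3 else obj$noise_sd,
      temperature = if (is.null(obj$temperature)) 3 else obj$temperature,
      lapse = if (is.null(obj$lapse)) 0.02 else obj$lapse,
      encoding = if (is.null(obj$encoding)) "saturating" else obj$encoding
    )
  } else if (all(c("asymptote", "decay_rate") %in% names(obj))) {
    retention_params(asymptote = obj$asymptote, decay_rate = obj$decay_rate,
                     chance = if (is.null(obj$chance)) 0.5 else obj$chance)
  } else stop_input("JSON config matches neither parameter schema")
}
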