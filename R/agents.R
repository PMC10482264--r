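# Learning agents. Agents are functional: `agent_act()` returns a response
# given the percept, `agent_learn()` returns the updated agent. Randomness
# comes from the RNG stream that run_task() seeds.

#' Agents
#'
#' Three agents generate behaviour on the scheduled tasks:
#' \describe{
#'   \item{`random_agent()`}{responds uniformly at random among the
#'     displayed options; the chance baseline.}
#'   \item{`trace_agent()`}{perceives only the (noisy) trace intensities at
#'     decision time, never the ordered sequence. On matching trials it
#'     chooses the option with the highest perceived intensity; on
#'     sequence-discrimination trials it holds linear action values
#'     \eqn{w_s \cdot (m_1, m_2, 1)} per response side over the two colour
#'     intensities, chooses by softmax, and updates the chosen side's
#'     weights by the delta rule
#'     \eqn{w \leftarrow w + \alpha (r - v) x}. With zero decay the AB and
#'     BA sequences produce identical intensity pairs, so they are
#'     indistinguishable to this agent by construction.}
#'   \item{`faithful_agent()`}{perceives the ordered sequence identity as a
#'     lossless key and keeps tabular action values per (key, side) updated
#'     by the delta rule, with an epsilon-greedy policy. AB and BA map to
#'     different keys.}
#' }
#'
#' @param params a [trace_params()] object (perceptual/choice parameters of
#'   the trace agent).
#' @param alpha delta-rule learning rate in (0, 1].
#' @param epsilon exploration probability of the epsilon-greedy policy.
#' @return an agent object (classes `trace_agent`, `faithful_agent` or
#'   `random_agent`, all inheriting `seqtrace_agent`).
#' @seealso [run_task()]
#' @name agents
NULL

#' @rdname agents
#' @export
random_agent <- function() {
  structure(list(), class = c("random_agent", "seqtrace_agent"))
}

#' @rdname agents
#' @export
trace_agent <- function(params = trace_params(), alpha = 0.02) {
  stopifnot(inherits(params, "trace_params"))
  assert_scalar_num(alpha, "alpha", lower = 0, upper = 1,
                    strict_lower = TRUE)
  structure(
    list(params = params, alpha = alpha,
         w = matrix(0, nrow = 2, ncol = 3,
                    dimnames = list(c("left", "right"), NULL))),
    class = c("trace_agent", "seqtrace_agent")
  )
}

#' @rdname agents
#' @param q_init optimistic initial action value of the faithful agent;
#'   makes an unrewarded error informative, so each sequence key costs at
#'   most one greedy error.
#' @export
faithful_agent <- function(alpha = 1, epsilon = 0.1, q_init = 0.5) {
  assert_scalar_num(alpha, "alpha", lower = 0, upper = 1,
                    strict_lower = TRUE)
  assert_scalar_num(epsilon, "epsilon", lower = 0, upper = 1)
  assert_scalar_num(q_init, "q_init", lower = 0)
  structure(
    list(alpha = alpha, epsilon = epsilon, q_init = q_init, q = list()),
    class = c("faithful_agent", "seqtrace_agent")
  )
}

# percept: list(kind = "matching"|"sequence", options, intensities,
#               features (sequence only: noisy colour intensities + bias),
#               key (trial_type)).
# agent_act returns list(response, percept) so learn sees the same percept.

agent_act <- function(agent, percept) UseMethod("agent_act")
agent_learn <- function(agent, percept, response, reward)
  UseMethod("agent_learn")

#' @export
agent_act.random_agent <- function(agent, percept) {
  percept$options[sample.int(length(percept$options), 1L)]
}
#' @export
agent_learn.random_agent <- function(agent, percept, response, reward) agent

#' @export
agent_act.trace_agent <- function(agent, percept) {
  p <- agent$params
  if (percept$kind == "matching") {
    noisy <- percept$intensities + stats::rnorm(length(percept$intensities),
                                                0, p$noise_sd)
    if (stats::runif(1) < p$lapse)
      return(percept$options[sample.int(length(percept$options), 1L)])
    percept$options[which.max(noisy)]
  } else {
    x <- percept$features
    v <- as.vector(agent$w %*% x)
    z <- p$temperature * v; z <- z - max(z)
    pr <- exp(z) / sum(exp(z))
    pr <- (1 - p$lapse) * pr + p$lapse / 2
    c("left", "right")[sample.int(2L, 1L, prob = pr)]
  }
}

#' @export
agent_learn.trace_agent <- function(agent, percept, response, reward) {
  if (percept$kind != "sequence") return(agent)
  x <- percept$features
  v <- sum(agent$w[response, ] * x)
  agent$w[response, ] <- agent$w[response, ] + agent$alpha * (reward - v) * x
  agent
}

#' @export
agent_act.faithful_agent <- function(agent, percept) {
  if (percept$kind != "sequence")
    return(percept$options[sample.int(length(percept$options), 1L)])
  if (stats::runif(1) < agent$epsilon)
    return(c("left", "right")[sample.int(2L, 1L)])
  q <- agent$q[[percept$key]]
  if (is.null(q)) q <- c(left = agent$q_init, right = agent$q_init)
  best <- which(q == max(q))
  names(q)[best[sample.int(length(best), 1L)]]
}

#' @export
agent_learn.faithful_agent <- function(agent, percept, response, reward) {
  if (percept$kind != "sequence") return(agent)
  q <- agent$q[[percept$key]]
  if (is.null(q)) q <- c(left = agent$q_init, right = agent$q_init)
  q[response] <- q[response] + agent$alpha * (reward - q[response])
  agent$q[[percept$key]] <- q
  agent
}
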