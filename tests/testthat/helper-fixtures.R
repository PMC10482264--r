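# Shared fixtures, built in code.

# Minimal trial log with given correct/incorrect pattern (sequence task
# shape); enough structure for the windowed/block summaries.
make_log <- function(correct, trial_type = "AB", session = 1L,
                     response = NULL, rewarded_option = NULL) {
  n <- length(correct)
  trial_type <- rep_len(trial_type, n)
  session <- rep_len(session, n)
  rewarded_option <- if (is.null(rewarded_option))
    ifelse(trial_type == "AB", "left", "right") else rep_len(rewarded_option, n)
  response <- if (is.null(response))
    ifelse(correct, rewarded_option,
           ifelse(rewarded_option == "left", "right", "left"))
    else rep_len(response, n)
  structure(data.frame(
    subject_id = "t", phase = "sequence_disc", session = session,
    block = (seq_len(n) - 1L) %/% 18L + 1L, trial = seq_len(n),
    trial_type = trial_type, delay_s = 0, dur_first_s = 1,
    dur_second_s = 1, isi_s = 0.3, sample_first_id = "blue",
    sample_second_id = "yellow", is_probe = FALSE, is_correction = FALSE,
    option_ids = "left|right", response = response,
    rewarded_option = rewarded_option, correct = correct,
    rewarded = correct, seed = 1L, stringsAsFactors = FALSE
  ), class = c("trial_log", "data.frame"))
}

# A faithful agent whose tabular values are pre-set to the correct mapping:
# deterministic, always correct (epsilon = 0).
perfect_sequence_agent <- function() {
  ag <- faithful_agent(alpha = 1, epsilon = 0)
  ag$q <- list(AB = c(left = 1, right = 0),
               AA = c(left = 0, right = 1),
               BA = c(left = 0, right = 1),
               BB = c(left = 0, right = 1))
  ag
}

# Exhaustive-enumeration oracle for the two-sided binomial p-value: count
# masses are accumulated by walking all 2^n success/failure sequences, then
# the minimum-likelihood rule is applied. Independent of dbinom.
binom_oracle <- function(k, n, p0) {
  mass <- numeric(n + 1)
  for (code in 0:(2^n - 1)) {
    j <- sum(bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L))
    mass[j + 1] <- mass[j + 1] + p0^j * (1 - p0)^(n - j)
  }
  min(1, sum(mass[mass <= mass[k + 1] * (1 + 1e-7)]))
}
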