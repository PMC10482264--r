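# Trial schedulers for the three behavioural paradigms. All schedulers are
# deterministic given (arguments, seed) and return a `trial_schedule`: a data
# frame with one row per planned trial.

SCHEDULE_COLS <- c("phase", "session", "block", "trial", "trial_type",
                   "delay_s", "dur_first_s", "dur_second_s", "isi_s",
                   "sample_first_id", "sample_second_id",
                   "is_probe", "is_correction",
                   "option_ids", "rewarded_option")

new_schedule <- function(df) {
  df <- df[, SCHEDULE_COLS]
  class(df) <- c("trial_schedule", "data.frame")
  df
}

# Default probe-duration design: first stimulus fixed at 1 s against three
# second-stimulus durations, and vice versa.
#' Default probe duration conditions
#'
#' The six (first, second) stimulus-duration pairs of the probe design:
#' three hold the first stimulus at 1 s while the second takes 0.5, 1.5 or
#' 4.5 s, and three hold the second at 1 s while the first takes 0.5, 1.5 or
#' 4.5 s.
#'
#' @return data frame with columns `d_first`, `d_second` (seconds).
#' @export
probe_conditions <- function() {
  data.frame(
    d_first  = c(0.5, 1.5, 4.5, 1.0, 1.0, 1.0),
    d_second = c(1.0, 1.0, 1.0, 0.5, 1.5, 4.5)
  )
}

probe_condition_label <- function(d_first, d_second) {
  sprintf("probe_%g_%g", d_first, d_second)
}

# Balanced shuffle: each element of `values` exactly n/length(values) times,
# order randomised. `n` must be a multiple of length(values).
balanced_shuffle <- function(values, n) {
  sample(rep(values, length.out = n))
}

#' Schedule a matching-to-sample phase
#'
#' Simultaneous or zero-delay matching-to-sample: a sample colour, then two
#' response options (one matching, one not) placed left/right. Within every
#' 10-trial window aligned to window starts, each sample colour appears 5
#' times and each correct side 5 times, with order randomised within the
#' window — the task's anti-bias randomisation. A final partial window is
#' drawn without the balance guarantee (with a warning).
#'
#' @param phase `"simultaneous_mts"` or `"zero_delay_mts"`.
#' @param n_trials number of trials (> 0).
#' @param seed integer seed; identical seeds give identical schedules.
#' @param sample_ids the two sample colours (default `c("blue", "yellow")`).
#' @param sample_duration sample presentation time in seconds (2 s for the
#'   zero-delay phase; for the simultaneous phase the sample stays on screen
#'   and the value records its nominal duration).
#' @return a `trial_schedule` data frame.
#' @export
schedule_mts <- function(phase = c("simultaneous_mts", "zero_delay_mts"),
                         n_trials, seed,
                         sample_ids = c("blue", "yellow"),
                         sample_duration = 2) {
  phase <- match.arg(phase)
  assert_scalar_num(n_trials, "n_trials", lower = 0, strict_lower = TRUE)
  if (length(sample_ids) != 2L || anyDuplicated(sample_ids))
    stop_input("'sample_ids' must be two distinct tokens")
  n_trials <- as.integer(n_trials)
  if (n_trials %% 10L != 0L)
    warning("n_trials is not a multiple of 10; final partial window is ",
            "drawn without the colour/side balance guarantee")
  with_seed(seed, {
    samples <- character(n_trials); sides <- character(n_trials)
    starts <- seq(1L, n_trials, by = 10L)
    for (s in starts) {
      len <- min(10L, n_trials - s + 1L)
      if (len == 10L) {
        samples[s:(s + 9L)] <- balanced_shuffle(sample_ids, 10L)
        sides[s:(s + 9L)] <- balanced_shuffle(c("left", "right"), 10L)
      } else {
        samples[s:(s + len - 1L)] <- sample(sample_ids, len, replace = TRUE)
        sides[s:(s + len - 1L)] <- sample(c("left", "right"), len,
                                          replace = TRUE)
      }
    }
    foil <- ifelse(samples == sample_ids[1], sample_ids[2], sample_ids[1])
    left <- ifelse(sides == "left", samples, foil)
    right <- ifelse(sides == "left", foil, samples)
    new_schedule(data.frame(
      phase = phase, session = 1L, block = (seq_len(n_trials) - 1L) %/% 10L + 1L,
      trial = seq_len(n_trials), trial_type = "delay_0",
      delay_s = 0, dur_first_s = sample_duration, dur_second_s = NA_real_,
      isi_s = NA_real_, sample_first_id = samples,
      sample_second_id = NA_character_,
      is_probe = FALSE, is_correction = FALSE,
      option_ids = paste(left, right, sep = "|"),
      rewarded_option = samples,
      stringsAsFactors = FALSE
    ))
  })
}

#' Schedule a delayed matching-to-sample phase
#'
#' Every second trial (the 1st, 3rd, ...) is a 0-second delay to keep reward
#' rates high; the remaining trials draw their delay from the non-zero set
#' in pseudo-random order, implemented as shuffled balanced blocks so that
#' long-run delay counts are equal. Sample colour and correct side keep the
#' 5/5 balance per 10-trial window.
#'
#' @param n_trials number of trials (> 0).
#' @param delays delay set in seconds; must contain 0 (default
#'   `c(0, 2, 5, 10)`).
#' @param seed integer seed.
#' @param sample_ids the two sample colours.
#' @param sample_duration sample presentation in seconds (default 2).
#' @return a `trial_schedule` data frame.
#' @export
schedule_delayed_mts <- function(n_trials, delays = c(0, 2, 5, 10), seed,
                                 sample_ids = c("blue", "yellow"),
                                 sample_duration = 2) {
  if (length(delays) == 0L) stop_input("'delays' must be non-empty")
  if (!0 %in% delays) stop_input("'delays' must contain 0")
  base <- schedule_mts("zero_delay_mts", n_trials, seed,
                       sample_ids = sample_ids,
                       sample_duration = sample_duration)
  n_trials <- nrow(base)
  nonzero <- sort(setdiff(delays, 0))
  delay <- numeric(n_trials)            # odd positions stay 0
  even <- seq_len(n_trials)[seq_len(n_trials) %% 2L == 0L]
  if (length(nonzero) > 0L && length(even) > 0L) {
    delay[even] <- with_seed(child_seed(seed, 1L), {
      n_full <- (length(even) %/% length(nonzero)) * length(nonzero)
      draws <- c(
        if (n_full > 0) as.vector(replicate(
          n_full / length(nonzero), sample(nonzero))),
        if (length(even) > n_full)
          sample(nonzero, length(even) - n_full, replace = TRUE)
      )
      draws
    })
  }
  base$phase <- "delayed_mts"
  base$delay_s <- delay
  base$trial_type <- sprintf("delay_%g", delay)
  base
}

#' Schedule the two-choice sequence-discrimination task
#'
#' Two 1-second stimuli separated by a 300 ms inter-stimulus interval,
#' followed by left/right response buttons. Trials come in blocks of 18
#' containing exactly 9 AB trials and three each of AA, BA and BB, in
#' randomised order; AB rewards the left button, the other three sequences
#' reward the right button.
#'
#' @param n_blocks number of 18-trial blocks (>= 1).
#' @param seed integer seed.
#' @param assignment named character vector mapping the roles `A` and `B` to
#'   colour tokens; the counterbalancing across subjects lives here.
#' @return a `trial_schedule` data frame.
#' @export
schedule_sequence_task <- function(n_blocks, seed,
                                   assignment = c(A = "yellow", B = "blue")) {
  assert_scalar_num(n_blocks, "n_blocks", lower = 1)
  if (!all(c("A", "B") %in% names(assignment)))
    stop_input("'assignment' must name colours for roles A and B")
  n_blocks <- as.integer(n_blocks)
  block_types <- c(rep("AB", 9L), rep("AA", 3L), rep("BA", 3L), rep("BB", 3L))
  with_seed(seed, {
    types <- as.vector(vapply(seq_len(n_blocks),
                              function(b) sample(block_types),
                              character(18L)))
    n <- length(types)
    first_role <- substr(types, 1L, 1L)
    second_role <- substr(types, 2L, 2L)
    new_schedule(data.frame(
      phase = "sequence_disc", session = 1L,
      block = rep(seq_len(n_blocks), each = 18L),
      trial = seq_len(n), trial_type = types,
      delay_s = 0, dur_first_s = 1, dur_second_s = 1, isi_s = 0.3,
      sample_first_id = unname(assignment[first_role]),
      sample_second_id = unname(assignment[second_role]),
      is_probe = FALSE, is_correction = FALSE,
      option_ids = "left|right",
      rewarded_option = ifelse(types == "AB", "left", "right"),
      stringsAsFactors = FALSE
    ))
  })
}

#' Schedule the probe phase of the trace-model test
#'
#' Baseline trials are 4-alternative matching-to-sample with a 1-second
#' sample drawn from a pool of pictorial stimuli and three random foils.
#' Every block of `block_len` trials contains exactly one unrewarded probe
#' trial at a uniformly random position within the block: a two-stimulus
#' sequence (both stimuli distinct, drawn at random from the pool) at one of
#' the duration conditions, followed by four options comprising both sample
#' stimuli and two non-matching stimuli.
#'
#' @param conditions data frame with columns `d_first`, `d_second` (seconds);
#'   defaults to [probe_conditions()].
#' @param reps_per_condition probe repetitions per condition (default 20).
#' @param block_len trials per block (default 10).
#' @param pool_size number of stimuli in the pool (default 20, >= 4).
#' @param seed integer seed.
#' @param isi inter-stimulus interval within probe sequences, seconds
#'   (default 0.3).
#' @return a `trial_schedule` data frame with
#'   `reps_per_condition * nrow(conditions)` probe trials among
#'   `reps_per_condition * nrow(conditions) * block_len` total trials.
#' @export
schedule_probe_phase <- function(conditions = probe_conditions(),
                                 reps_per_condition = 20, block_len = 10,
                                 pool_size = 20, seed, isi = 0.3) {
  if (!is.data.frame(conditions) ||
      !all(c("d_first", "d_second") %in% names(conditions)) ||
      nrow(conditions) < 1L)
    stop_input("'conditions' must be a data frame with d_first, d_second")
  assert_scalar_num(reps_per_condition, "reps_per_condition", lower = 1)
  assert_scalar_num(block_len, "block_len", lower = 2)
  assert_scalar_num(pool_size, "pool_size", lower = 4)
  assert_scalar_num(isi, "isi", lower = 0)
  pool <- sprintf("stim%02d", seq_len(pool_size))
  n_blocks <- as.integer(reps_per_condition) * nrow(conditions)
  block_len <- as.integer(block_len)
  with_seed(seed, {
    cond_idx <- sample(rep(seq_len(nrow(conditions)), reps_per_condition))
    probe_pos <- sample.int(block_len, n_blocks, replace = TRUE)
    rows <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      ci <- cond_idx[b]
      d1 <- conditions$d_first[ci]; d2 <- conditions$d_second[ci]
      is_probe <- seq_len(block_len) == probe_pos[b]
      opts <- character(block_len)
      s_first <- character(block_len); s_second <- rep(NA_character_, block_len)
      rewarded <- character(block_len)
      for (i in seq_len(block_len)) {
        if (is_probe[i]) {
          draw <- sample(pool, 4L)      # samples 1,2 + two foils
          s_first[i] <- draw[1L]; s_second[i] <- draw[2L]
          opts[i] <- paste(sample(draw), collapse = "|")
          rewarded[i] <- NA_character_  # probes are never rewarded
        } else {
          draw <- sample(pool, 4L)      # sample + three foils
          s_first[i] <- draw[1L]
          opts[i] <- paste(sample(draw), collapse = "|")
          rewarded[i] <- draw[1L]
        }
      }
      rows[[b]] <- data.frame(
        phase = "probe_mts", session = 1L, block = b,
        trial = (b - 1L) * block_len + seq_len(block_len),
        trial_type = ifelse(is_probe, probe_condition_label(d1, d2),
                            "baseline"),
        delay_s = 0,
        dur_first_s = ifelse(is_probe, d1, 1),
        dur_second_s = ifelse(is_probe, d2, NA_real_),
        isi_s = ifelse(is_probe, isi, NA_real_),
        sample_first_id = s_first, sample_second_id = s_second,
        is_probe = is_probe, is_correction = FALSE,
        option_ids = opts, rewarded_option = rewarded,
        stringsAsFactors = FALSE
      )
    }
    new_schedule(do.call(rbind, rows))
  })
}

#' Assign daily sessions to a schedule
#'
#' Optionally caps the number of trials per session (the study ran at most
#' 120 trials per individual per day); off by default in the schedulers.
#'
#' @param schedule a `trial_schedule`.
#' @param cap maximum trials per session.
#' @return the schedule with its `session` column rewritten.
#' @export
assign_sessions <- function(schedule, cap = 120) {
  assert_scalar_num(cap, "cap", lower = 1)
  schedule$session <- (seq_len(nrow(schedule)) - 1L) %/% as.integer(cap) + 1L
  schedule
}
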