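# Executes a schedule with an agent, producing a trial log.

LOG_COLS <- c("subject_id", "phase", "session", "block", "trial",
              "trial_type", "delay_s", "dur_first_s", "dur_second_s",
              "isi_s", "sample_first_id", "sample_second_id",
              "is_probe", "is_correction", "option_ids", "response",
              "rewarded_option", "correct", "rewarded", "seed")

#' Run an agent through a schedule
#'
#' Executes the trials of a schedule in order. On each trial the agent
#' perceives either the trace intensities of the displayed options
#' (matching trials) or the noisy colour-trace intensities at decision time
#' (sequence trials), responds, and — on rewarded trials — learns from the
#' outcome. Probe trials are recorded but never rewarded and trigger no
#' learning. With `correction = TRUE`, an incorrect response on a
#' (non-probe) sequence trial re-inserts the same trial, flagged
#' `is_correction`, until the response is correct — the study's correction
#' procedure.
#'
#' @param agent an agent from [trace_agent()], [faithful_agent()] or
#'   [random_agent()].
#' @param schedule a `trial_schedule` from one of the schedulers.
#' @param params a [trace_params()] object governing the stimulus-to-trace
#'   mapping (and perceptual noise on sequence trials); defaults to the
#'   trace agent's own parameters, or `trace_params()` otherwise.
#' @param correction enable correction trials on the sequence task.
#' @param seed integer seed; the single source of randomness for the run.
#' @param subject_id token recorded in the log.
#' @return a `trial_log`: a data frame with one row per executed trial
#'   (including correction trials), in execution order.
#' @examples
#' sched <- schedule_sequence_task(2, seed = 1)
#' log <- run_task(faithful_agent(), sched, seed = 1, correction = TRUE)
#' mean(log$correct)
#' @export
run_task <- function(agent, schedule, params = NULL, correction = FALSE,
                     seed, subject_id = "subj1") {
  stopifnot(inherits(agent, "seqtrace_agent"))
  if (!is.data.frame(schedule) || nrow(schedule) == 0L)
    stop_input("'schedule' must be a non-empty trial schedule")
  if (is.null(params)) {
    params <- if (inherits(agent, "trace_agent")) agent$params
              else trace_params()
  }
  stopifnot(inherits(params, "trace_params"))

  n <- nrow(schedule)
  phase <- schedule$phase; type <- schedule$trial_type
  delay <- schedule$delay_s; d1 <- schedule$dur_first_s
  d2 <- schedule$dur_second_s; isi <- schedule$isi_s
  s1 <- schedule$sample_first_id; s2 <- schedule$sample_second_id
  probe <- schedule$is_probe; opts_str <- schedule$option_ids
  rewarded_opt <- schedule$rewarded_option
  session <- schedule$session; block <- schedule$block
  opts_list <- strsplit(opts_str, "|", fixed = TRUE)

  cap <- 2L * n + 64L
  idx <- integer(cap); corr_flag <- logical(cap)
  resp <- character(cap); corr <- logical(cap); rew <- logical(cap)
  out_i <- 0L
  push <- function(i, is_corr, r, ok, rw) {
    out_i <<- out_i + 1L
    if (out_i > length(idx)) {          # grow
      grow <- length(idx)
      idx <<- c(idx, integer(grow)); corr_flag <<- c(corr_flag, logical(grow))
      resp <<- c(resp, character(grow)); corr <<- c(corr, logical(grow))
      rew <<- c(rew, logical(grow))
    }
    idx[out_i] <<- i; corr_flag[out_i] <<- is_corr
    resp[out_i] <<- r; corr[out_i] <<- ok; rew[out_i] <<- rw
  }

  seq_colours <- if (any(phase == "sequence_disc"))
    sort(unique(c(s1[phase == "sequence_disc"],
                  s2[phase == "sequence_disc"])))

  build_percept <- function(i) {
    options <- opts_list[[i]]
    if (phase[i] == "sequence_disc") {
      # decayed intensities of the two colours at options onset
      t_dec <- isi[i] + d2[i]
      m <- c(0, 0); names(m) <- seq_colours
      m[s1[i]] <- m[s1[i]] + encode_intensity(d1[i], params) *
        exp(-params$decay * t_dec)
      m[s2[i]] <- m[s2[i]] + encode_intensity(d2[i], params)
      feat <- c(m + stats::rnorm(2, 0, params$noise_sd), 1)
      list(kind = "sequence", options = options, features = feat,
           key = type[i])
    } else {
      intens <- numeric(length(options)); names(intens) <- options
      if (probe[i]) {
        intens[s1[i]] <- encode_intensity(d1[i], params) *
          exp(-params$decay * (isi[i] + d2[i]))
        intens[s2[i]] <- encode_intensity(d2[i], params)
      } else {
        intens[s1[i]] <- encode_intensity(d1[i], params) *
          exp(-params$decay * delay[i])
      }
      list(kind = "matching", options = options, intensities = intens,
           key = type[i])
    }
  }

  with_seed(seed, {
    for (i in seq_len(n)) {
      is_corr <- FALSE
      repeat {
        percept <- build_percept(i)
        r <- agent_act(agent, percept)
        if (!r %in% percept$options && !(phase[i] == "sequence_disc"))
          stop("agent responded with an option not on screen: ", r)
        if (phase[i] == "sequence_disc" && !r %in% c("left", "right"))
          stop("agent responded with an option not on screen: ", r)
        ok <- if (probe[i]) NA else r == rewarded_opt[i]
        rw <- isTRUE(ok)
        push(i, is_corr, r, ok, rw)
        if (!probe[i])
          agent <- agent_learn(agent, percept, r, as.numeric(rw))
        if (correction && phase[i] == "sequence_disc" && !probe[i] &&
            !isTRUE(ok)) {
          is_corr <- TRUE               # repeat the same spec
        } else break
      }
    }
  })

  keep <- seq_len(out_i)
  idx <- idx[keep]
  log <- data.frame(
    subject_id = subject_id, phase = phase[idx], session = session[idx],
    block = block[idx], trial = seq_along(idx), trial_type = type[idx],
    delay_s = delay[idx], dur_first_s = d1[idx], dur_second_s = d2[idx],
    isi_s = isi[idx], sample_first_id = s1[idx], sample_second_id = s2[idx],
    is_probe = probe[idx], is_correction = corr_flag[keep],
    option_ids = opts_str[idx], response = resp[keep],
    rewarded_option = rewarded_opt[idx], correct = corr[keep],
    rewarded = rew[keep], seed = as.integer(seed),
    stringsAsFactors = FALSE
  )
  log$correct[log$is_probe] <- NA
  structure(log, class = c("trial_log", "data.frame"))
}

#' Write / read trial logs as CSV
#'
#' One row per trial, header mandatory, UTF-8. The reader restores the
#' `trial_log` class and column types; a written log read back is identical
#' to the original.
#'
#' @param log a `trial_log` data frame.
#' @param path CSV file path.
#' @return `read_trial_log()` returns a `trial_log`; `write_trial_log()`
#'   returns `path` invisibly.
#' @export
write_trial_log <- function(log, path) {
  stopifnot(is.data.frame(log))
  utils::write.csv(as.data.frame(log)[, LOG_COLS], path, row.names = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  log <- utils::read.csv(
    path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
    colClasses = c(
      subject_id = "character", phase = "character", session = "integer",
      block = "integer", trial = "integer", trial_type = "character",
      delay_s = "numeric", dur_first_s = "numeric",
      dur_second_s = "numeric", isi_s = "numeric",
      sample_first_id = "character", sample_second_id = "character",
      is_probe = "logical", is_correction = "logical",
      option_ids = "character", response = "character",
      rewarded_option = "character", correct = "logical",
      rewarded = "logical", seed = "integer"
    ), na.strings = ""
  )
  log$rewarded[is.na(log$rewarded)] <- FALSE
  structure(log, class = c("trial_log", "data.frame"))
}
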