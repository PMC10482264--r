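# Synthetic study generator: complete, study-shaped trial logs with known
# ground truth, plus the published probe-count tables as fixtures.

#' Configuration of a synthetic study
#'
#' Describes a full synthetic study: four bonobo-like subjects driven by
#' the trace model (delayed matching-to-sample, sequence discrimination
#' with correction trials, probe phase) and five human-like subjects driven
#' by faithful sequence memory (sequence discrimination only). Per-subject
#' parameters are jittered around the configured means to emulate
#' between-subject spread.
#'
#' @param n_trace_subjects bonobo-like subjects (default 4).
#' @param n_faithful_subjects human-like subjects (default 5).
#' @param dmts_trials delayed matching-to-sample trials per trace subject
#'   (default 1200; half are 0-s delays).
#' @param dmts_delays delay set in seconds (default `c(0, 2, 5, 10)`).
#' @param seq_blocks 18-trial sequence-task blocks per subject (default
#'   128, i.e. 2304 scheduled trials — every subject exceeds 2300).
#' @param probe_reps probe repetitions per duration condition (default 20).
#' @param retention mean [retention_params()] of the trace subjects.
#' @param trace mean [trace_params()] of the trace subjects' perception and
#'   learning (the default noise s.d. of 1.2 places the agents in the
#'   near-chance sequence-learning regime the bonobos showed).
#' @param trace_alpha delta-rule learning rate of the trace agents.
#' @param faithful_alpha,faithful_epsilon faithful-agent learning rate and
#'   exploration probability.
#' @param jitter_sd relative s.d. of the between-subject parameter jitter
#'   (default 0.1; applied multiplicatively to asymptote, decay rates and
#'   noise).
#' @param seed master seed; all per-subject seeds derive from it.
#' @return a `study_config` list.
#' @export
study_config <- function(n_trace_subjects = 4, n_faithful_subjects = 5,
                         dmts_trials = 1200, dmts_delays = c(0, 2, 5, 10),
                         seq_blocks = 128, probe_reps = 20,
                         retention = retention_params(0.7, 0.25, 0.5),
                         trace = trace_params(gain = 1, decay = 0.5,
                                              noise_sd = 1.2,
                                              temperature = 3,
                                              lapse = 0.02),
                         trace_alpha = 0.02,
                         faithful_alpha = 1, faithful_epsilon = 0.1,
                         jitter_sd = 0.1, seed = 20220401) {
  assert_scalar_num(n_trace_subjects, "n_trace_subjects", lower = 1)
  assert_scalar_num(n_faithful_subjects, "n_faithful_subjects", lower = 0)
  assert_scalar_num(dmts_trials, "dmts_trials", lower = 1)
  assert_scalar_num(seq_blocks, "seq_blocks", lower = 1)
  assert_scalar_num(probe_reps, "probe_reps", lower = 1)
  assert_scalar_num(jitter_sd, "jitter_sd", lower = 0)
  structure(
    list(n_trace_subjects = as.integer(n_trace_subjects),
         n_faithful_subjects = as.integer(n_faithful_subjects),
         dmts_trials = as.integer(dmts_trials), dmts_delays = dmts_delays,
         seq_blocks = as.integer(seq_blocks),
         probe_reps = as.integer(probe_reps),
         retention = retention, trace = trace, trace_alpha = trace_alpha,
         faithful_alpha = faithful_alpha,
         faithful_epsilon = faithful_epsilon,
         jitter_sd = jitter_sd, seed = seed),
    class = "study_config"
  )
}

jitter_pos <- function(x, rel_sd) x * exp(stats::rnorm(1, 0, rel_sd))

# Synthetic DMTS log: responses are Bernoulli draws at the subject's
# retention-curve accuracy for each trial's delay.
synth_dmts_log <- function(rp, n_trials, delays, seed, subject_id) {
  sched <- schedule_delayed_mts(n_trials, delays, seed)
  with_seed(child_seed(seed, 7L), {
    p <- retention_curve(sched$delay_s, rp)
    correct <- stats::runif(nrow(sched)) < p
    opts <- strsplit(sched$option_ids, "|", fixed = TRUE)
    foil <- vapply(seq_len(nrow(sched)), function(i)
      setdiff(opts[[i]], sched$rewarded_option[i])[1], character(1))
    log <- data.frame(
      subject_id = subject_id, phase = sched$phase, session = sched$session,
      block = sched$block, trial = sched$trial,
      trial_type = sched$trial_type, delay_s = sched$delay_s,
      dur_first_s = sched$dur_first_s, dur_second_s = sched$dur_second_s,
      isi_s = sched$isi_s, sample_first_id = sched$sample_first_id,
      sample_second_id = sched$sample_second_id,
      is_probe = FALSE, is_correction = FALSE,
      option_ids = sched$option_ids,
      response = ifelse(correct, sched$rewarded_option, foil),
      rewarded_option = sched$rewarded_option,
      correct = correct, rewarded = correct, seed = as.integer(seed),
      stringsAsFactors = FALSE
    )
    structure(log, class = c("trial_log", "data.frame"))
  })
}

#' Generate a complete synthetic study
#'
#' Produces one trial log per subject and paradigm under a [study_config()],
#' together with a ground-truth record of every generating parameter and
#' seed. Trace-model subjects yield delayed matching-to-sample logs whose
#' per-delay accuracy follows their retention curve, sequence-task logs
#' produced by a [trace_agent()] under the correction procedure (near
#' chance on AB vs BA by construction), and probe-phase logs produced by
#' trace-based choice. Faithful subjects yield sequence-task logs that
#' reach the 80%-over-20-trials criterion rapidly. Regeneration with the
#' same config is byte-identical.
#'
#' @param config a [study_config()].
#' @return a `synthetic_study` list: `logs` (named list of `trial_log`s,
#'   names like `"bonobo1_dmts"`), `ground_truth` (list), `config`.
#' @seealso [write_study()]
#' @export
generate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  logs <- list(); truth <- list(subjects = list(), master_seed = config$seed)
  half <- ceiling(config$n_trace_subjects / 2)
  for (i in seq_len(config$n_trace_subjects)) {
    sid <- sprintf("bonobo%d", i)
    s_seed <- child_seed(config$seed, i)
    rp <- with_seed(child_seed(s_seed, 1L), retention_params(
      asymptote = min(1, jitter_pos(config$retention$asymptote,
                                    config$jitter_sd)),
      decay_rate = jitter_pos(config$retention$decay_rate, config$jitter_sd),
      chance = config$retention$chance))
    tp <- with_seed(child_seed(s_seed, 2L), trace_params(
      gain = config$trace$gain,
      decay = jitter_pos(config$trace$decay, config$jitter_sd),
      noise_sd = jitter_pos(config$trace$noise_sd, config$jitter_sd),
      temperature = config$trace$temperature,
      lapse = config$trace$lapse))
    # counterbalanced colour assignment, metadata only
    assignment <- if (i <= half) c(A = "yellow", B = "blue")
                  else c(A = "blue", B = "yellow")

    logs[[paste0(sid, "_dmts")]] <- synth_dmts_log(
      rp, config$dmts_trials, config$dmts_delays,
      child_seed(s_seed, 3L), sid)

    seq_sched <- schedule_sequence_task(config$seq_blocks,
                                        child_seed(s_seed, 4L), assignment)
    logs[[paste0(sid, "_seqdisc")]] <- run_task(
      trace_agent(tp, alpha = config$trace_alpha), seq_sched,
      correction = TRUE, seed = child_seed(s_seed, 5L), subject_id = sid)

    probe_sched <- schedule_probe_phase(reps_per_condition = config$probe_reps,
                                        seed = child_seed(s_seed, 6L))
    logs[[paste0(sid, "_probe")]] <- run_task(
      trace_agent(tp, alpha = config$trace_alpha), probe_sched,
      seed = child_seed(s_seed, 8L), subject_id = sid)

    truth$subjects[[sid]] <- list(
      kind = "trace", seed = s_seed, retention = unclass(rp),
      trace = unclass(tp), alpha = config$trace_alpha,
      assignment = as.list(assignment))
  }
  for (i in seq_len(config$n_faithful_subjects)) {
    sid <- sprintf("human%d", i)
    s_seed <- child_seed(config$seed, 1000L + i)
    assignment <- if (i %% 2L == 1L) c(A = "blue", B = "orange")
                  else c(A = "orange", B = "blue")
    seq_sched <- schedule_sequence_task(config$seq_blocks,
                                        child_seed(s_seed, 4L), assignment)
    logs[[paste0(sid, "_seqdisc")]] <- run_task(
      faithful_agent(config$faithful_alpha, config$faithful_epsilon),
      seq_sched, correction = TRUE, seed = child_seed(s_seed, 5L),
      subject_id = sid)
    truth$subjects[[sid]] <- list(
      kind = "faithful", seed = s_seed, alpha = config$faithful_alpha,
      epsilon = config$faithful_epsilon, assignment = as.list(assignment))
  }
  structure(list(logs = logs, ground_truth = truth, config = config),
            class = "synthetic_study")
}

#' Write a synthetic study to disk
#'
#' One CSV per subject/paradigm plus `ground_truth.json` and a short
#' `README.txt` describing the bundle.
#'
#' @param study a `synthetic_study` from [generate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(study$logs))
    write_trial_log(study$logs[[nm]], file.path(dir, paste0(nm, ".csv")))
  jsonlite::write_json(study$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(
    "Synthetic behavioural study bundle.",
    "One CSV trial log per subject and paradigm",
    "(<subject>_<dmts|seqdisc|probe>.csv); column schema as documented in",
    "?write_trial_log. ground_truth.json records every generating",
    "parameter and seed."), file.path(dir, "README.txt"))
  invisible(dir)
}

#' Published probe-choice counts of the two bonobo subjects
#'
#' The 6 x 2 tables of probe-trial choices (first-sample vs second-sample
#' stimulus per duration condition) observed for the two bonobos, Kanzi and
#' Teco, in the trace-model test this package models, as
#' [contingency_table()] fixtures. Row order matches [probe_conditions()].
#' Kanzi chose a sample stimulus on 116 of his 120 probes, Teco on 94.
#'
#' @return a named list of two `contingency_table`s (`kanzi`, `teco`).
#' @seealso [reference_probe_log()]
#' @export
reference_probe_counts <- function() {
  conds <- probe_conditions()
  labels <- probe_condition_label(conds$d_first, conds$d_second)
  mk <- function(m) contingency_table(
    m, row_labels = labels, col_labels = c("chose_first", "chose_second"))
  list(
    kanzi = mk(rbind(c(6, 14), c(5, 15), c(8, 11),
                     c(6, 13), c(1, 18), c(3, 16))),
    teco  = mk(rbind(c(4, 13), c(4, 12), c(4, 11),
                     c(7, 7), c(3, 12), c(3, 14)))
  )
}

#' Probe trial log consistent with the published counts
#'
#' Builds a synthetic probe-phase `trial_log` whose per-condition choice
#' counts reproduce the published table for the given subject exactly
#' (20 probes per condition; responses beyond the two sample columns go to
#' a non-matching option). The within-condition response order is invented
#' and non-informative — only the counts are data.
#'
#' @param subject `"kanzi"` or `"teco"`.
#' @param reps_per_condition probes per condition in the source design
#'   (20).
#' @return a `trial_log` of probe trials.
#' @export
reference_probe_log <- function(subject = c("kanzi", "teco"),
                                reps_per_condition = 20) {
  subject <- match.arg(subject)
  tab <- reference_probe_counts()[[subject]]
  conds <- probe_conditions()
  rows <- list()
  for (i in seq_len(nrow(conds))) {
    k1 <- tab[i, 1]; k2 <- tab[i, 2]
    k_miss <- reps_per_condition - k1 - k2
    if (k_miss < 0) stop_input("counts exceed reps_per_condition")
    response <- c(rep("s1", k1), rep("s2", k2), rep("f1", k_miss))
    rows[[i]] <- data.frame(
      subject_id = subject, phase = "probe_mts", session = 1L,
      block = (i - 1L) * reps_per_condition + seq_len(reps_per_condition),
      trial = 0L,
      trial_type = probe_condition_label(conds$d_first[i],
                                         conds$d_second[i]),
      delay_s = 0, dur_first_s = conds$d_first[i],
      dur_second_s = conds$d_second[i], isi_s = 0.3,
      sample_first_id = "s1", sample_second_id = "s2",
      is_probe = TRUE, is_correction = FALSE,
      option_ids = "s1|s2|f1|f2", response = response,
      rewarded_option = NA_character_, correct = NA, rewarded = FALSE,
      seed = 0L, stringsAsFactors = FALSE
    )
  }
  log <- do.call(rbind, rows)
  log$trial <- seq_len(nrow(log))
  structure(log, class = c("trial_log", "data.frame"))
}
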