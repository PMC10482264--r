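# First-principles implementations of the behavioural-count statistics:
# exact two-sided binomial test (minimum-likelihood method) and the Pearson
# chi-squared test of homogeneity, plus trial-log summaries.

new_test_result <- function(statistic, df, p_value, method, n) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method, n = n),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s\n", x$method))
  if (!is.null(x$statistic) && !is.na(x$statistic))
    cat(sprintf("  statistic = %.4f%s\n", x$statistic,
                if (!is.null(x$df) && !is.na(x$df))
                  sprintf(", df = %d", x$df) else ""))
  cat(sprintf("  n = %d, p = %.4g\n", x$n, x$p_value))
  invisible(x)
}

#' Exact two-sided binomial test
#'
#' Exact two-sided p-value for `k` successes in `n` Bernoulli(p0) trials by
#' the minimum-likelihood method: the p-value sums the probabilities of all
#' outcomes whose probability mass does not exceed that of the observed
#' count (the convention of standard statistical software).
#'
#' @param k observed successes (0 <= k <= n).
#' @param n number of trials (> 0).
#' @param p0 null success probability, strictly in (0, 1); default 0.5.
#' @return a `test_result` with the p-value (statistic is the observed
#'   proportion).
#' @examples
#' binom_test_two_sided(116, 120)   # p far below 0.001
#' @export
binom_test_two_sided <- function(k, n, p0 = 0.5) {
  assert_scalar_num(n, "n", lower = 1)
  assert_scalar_num(k, "k", lower = 0, upper = n)
  if (!is.numeric(p0) || length(p0) != 1L || p0 <= 0 || p0 >= 1)
    stop_input("'p0' must lie strictly between 0 and 1")
  k <- as.integer(k); n <- as.integer(n)
  mass <- stats::dbinom(0:n, n, p0)
  # relative tolerance guards ties lost to floating point (as binom.test)
  p <- sum(mass[mass <= mass[k + 1L] * (1 + 1e-7)])
  new_test_result(statistic = k / n, df = NA_integer_,
                  p_value = min(1, p),
                  method = sprintf("Exact binomial test (two-sided, p0 = %g)",
                                   p0),
                  n = n)
}

#' Contingency table of choice counts
#'
#' @param counts matrix of non-negative integer counts.
#' @param row_labels,col_labels optional dimension labels.
#' @return a `contingency_table` (an integer matrix with dimnames).
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_input("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  if (!is.null(row_labels)) rownames(counts) <- row_labels
  if (!is.null(col_labels)) colnames(counts) <- col_labels
  structure(counts, class = c("contingency_table", class(counts)))
}

#' Pearson chi-squared test on a contingency table
#'
#' Pearson statistic \eqn{\sum (O - E)^2 / E} with expected counts from the
#' row/column margins and df = (r - 1)(c - 1). No continuity correction by
#' default; the optional Yates correction applies to 2 x 2 tables only.
#'
#' @param table a matrix of counts (at least 2 x 2), e.g. from
#'   [contingency_table()] or [probe_tables()].
#' @param correction apply the Yates continuity correction (2 x 2 only).
#' @return a `test_result` with statistic, df and p-value.
#' @examples
#' tab <- contingency_table(rbind(c(4, 13), c(4, 12), c(4, 11),
#'                                c(7, 7), c(3, 12), c(3, 14)))
#' chisq_contingency(tab)   # 5.06 on 5 df
#' @export
chisq_contingency <- function(table, correction = FALSE) {
  O <- unclass(as.matrix(table))
  if (nrow(O) < 2L || ncol(O) < 2L)
    stop_input("table must be at least 2 x 2")
  if (any(O < 0)) stop_input("counts must be non-negative")
  rs <- rowSums(O); cs <- colSums(O)
  if (any(rs == 0))
    stop_input("degenerate table: row margin %d is zero", which(rs == 0)[1])
  if (any(cs == 0))
    stop_input("degenerate table: column margin %d is zero",
               which(cs == 0)[1])
  E <- outer(rs, cs) / sum(O)
  dev <- abs(O - E)
  if (correction && nrow(O) == 2L && ncol(O) == 2L)
    dev <- pmax(0, dev - 0.5)
  stat <- sum(dev^2 / E)
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  new_test_result(statistic = stat, df = df,
                  p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                  method = "Pearson chi-squared test", n = sum(O))
}

#' Earliest trial meeting a windowed learning criterion
#'
#' Scans a trial log for the first trial at which the proportion correct
#' over the last `window` trials within the same session reaches
#' `threshold` (at least `ceiling(threshold * window)` correct). Sessions
#' are never straddled. Probe trials (no defined correct response) are
#' excluded.
#'
#' @param log a `trial_log`.
#' @param window window length in trials (default 20).
#' @param threshold required proportion correct (default 0.8).
#' @return the (log-order) trial index at which the criterion is first met,
#'   or `NA_integer_` if never.
#' @export
windowed_criterion <- function(log, window = 20, threshold = 0.8) {
  assert_scalar_num(window, "window", lower = 1)
  assert_scalar_num(threshold, "threshold", lower = 0, upper = 1)
  window <- as.integer(window)
  need <- ceiling(threshold * window)
  usable <- which(!is.na(log$correct))
  if (length(usable) == 0L) return(NA_integer_)
  for (sess in unique(log$session[usable])) {
    rows <- usable[log$session[usable] == sess]
    x <- as.integer(log$correct[rows])
    if (length(x) < window) next
    cs <- cumsum(x)
    wins <- cs[window:length(x)] -
      c(0, cs)[seq_len(length(x) - window + 1L)]
    hit <- which(wins >= need)
    if (length(hit) > 0L)
      return(log$trial[rows[hit[1L] + window - 1L]])
  }
  NA_integer_
}

#' Block-wise performance of a sequence-task log
#'
#' Proportion of correct trials within consecutive blocks of `block` trials
#' (default 120, the study's reporting block), overall and per trial type.
#' Correction trials are included, as in the study's performance measure. A
#' final partial block is reported with its own `n` and flagged.
#'
#' @param log a `trial_log` from the sequence task.
#' @param block block length in trials.
#' @param by_type also stratify by `trial_type`.
#' @return a `performance_series` data frame with columns `block_index`,
#'   `trial_type` (`"all"` for the pooled rows), `n`, `k`,
#'   `proportion_correct`, `partial`.
#' @export
block_performance <- function(log, block = 120, by_type = TRUE) {
  if (!is.data.frame(log) || nrow(log) == 0L)
    stop_input("'log' must be a non-empty trial log")
  assert_scalar_num(block, "block", lower = 1)
  block <- as.integer(block)
  log <- log[!is.na(log$correct), , drop = FALSE]
  bi <- (seq_len(nrow(log)) - 1L) %/% block + 1L
  n_full <- nrow(log) %/% block
  agg <- function(rows, type, b) {
    data.frame(block_index = b, trial_type = type, n = length(rows),
               k = sum(log$correct[rows]),
               proportion_correct = mean(log$correct[rows]),
               partial = b > n_full, stringsAsFactors = FALSE)
  }
  out <- list()
  for (b in unique(bi)) {
    rows <- which(bi == b)
    out[[length(out) + 1L]] <- agg(rows, "all", b)
    if (by_type) {
      for (tt in sort(unique(log$trial_type[rows])))
        out[[length(out) + 1L]] <-
          agg(rows[log$trial_type[rows] == tt], tt, b)
    }
  }
  structure(do.call(rbind, out),
            class = c("performance_series", "data.frame"))
}

#' Probe-trial choice tables
#'
#' Cross-tabulates the probe trials of a log: one row per probe duration
#' condition, columns counting choices of the first-sample vs the
#' second-sample stimulus. Probe responses to non-matching stimuli appear
#' in neither column but count towards the probe total `n`; `k` counts
#' probes on which either sample stimulus was chosen.
#'
#' @param log a `trial_log` containing probe trials.
#' @return a list with `table` (a `contingency_table`, rows in the order the
#'   conditions first appear sorted by label), `matching_count` (k),
#'   `probe_total` (n).
#' @export
probe_tables <- function(log) {
  pr <- log[log$is_probe, , drop = FALSE]
  if (nrow(pr) == 0L) stop_input("log contains no probe trials")
  chose_first <- pr$response == pr$sample_first_id
  chose_second <- pr$response == pr$sample_second_id
  conds <- sort(unique(pr$trial_type))
  counts <- t(vapply(conds, function(cc) {
    rows <- pr$trial_type == cc
    c(sum(chose_first[rows]), sum(chose_second[rows]))
  }, numeric(2)))
  tab <- contingency_table(counts, row_labels = conds,
                           col_labels = c("chose_first", "chose_second"))
  list(table = tab,
       matching_count = sum(chose_first | chose_second),
       probe_total = nrow(pr))
}

#' Per-delay performance summary of a delayed matching-to-sample log
#'
#' For each delay, the number correct, total, proportion, Wilson 95%
#' confidence interval, and the exact two-sided binomial test against
#' chance (p0 = 0.5) — the retention summary of the delayed
#' matching-to-sample results.
#'
#' @param log a `trial_log` from the delayed matching-to-sample task.
#' @param conf confidence level for the Wilson interval.
#' @return data frame with columns `delay_s`, `k`, `n`,
#'   `proportion_correct`, `ci_lower`, `ci_upper`, `p_value`.
#' @export
delay_performance <- function(log, conf = 0.95) {
  log <- log[!is.na(log$correct), , drop = FALSE]
  delays <- sort(unique(log$delay_s))
  out <- lapply(delays, function(d) {
    rows <- log$delay_s == d
    k <- sum(log$correct[rows]); n <- sum(rows)
    ci <- wilson_ci(k, n, conf)
    data.frame(delay_s = d, k = k, n = n, proportion_correct = k / n,
               ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
               p_value = binom_test_two_sided(k, n, 0.5)$p_value)
  })
  do.call(rbind, out)
}

#' Balanced discrimination accuracy between two trial types
#'
#' Measures whether a sequence-task log discriminates two trial types
#' (default AB vs BA) as the balanced accuracy
#' \eqn{(\hat{P}(\mathrm{correct}\mid t_1) +
#'       \hat{P}(\mathrm{correct}\mid t_2))/2}.
#' Because the two types reward opposite sides, any response policy that
#' cannot tell the types apart — however side-biased — has expected
#' balanced accuracy 0.5, making this the right chance-level statistic
#' when reward frequencies are unequal. The chance band is the two-sided
#' normal band around 0.5 with the null variance
#' \eqn{\hat{p}(1-\hat{p})\,(1/(4n_1) + 1/(4n_2))}, where \eqn{\hat{p}} is
#' the pooled proportion of first-side responses.
#'
#' @param log a `trial_log` from the sequence task.
#' @param types two trial types rewarding opposite sides (default
#'   `c("AB", "BA")`).
#' @param conf band confidence level (default 0.99).
#' @return list with `balanced_accuracy`, `lower`, `upper`, `within`
#'   (logical), `n1`, `n2`.
#' @export
discrimination_accuracy <- function(log, types = c("AB", "BA"),
                                    conf = 0.99) {
  if (length(types) != 2L) stop_input("'types' must name two trial types")
  r1 <- log$trial_type == types[1] & !is.na(log$correct)
  r2 <- log$trial_type == types[2] & !is.na(log$correct)
  n1 <- sum(r1); n2 <- sum(r2)
  if (n1 == 0L || n2 == 0L)
    stop_input("log lacks trials of type %s or %s", types[1], types[2])
  acc <- (mean(log$correct[r1]) + mean(log$correct[r2])) / 2
  side1 <- log$rewarded_option[which(r1)[1]]   # side rewarded for type 1
  p_hat <- mean(log$response[r1 | r2] == side1)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(max(p_hat * (1 - p_hat), 1e-12) *
                     (1 / (4 * n1) + 1 / (4 * n2)))
  list(balanced_accuracy = acc, lower = 0.5 - half, upper = 0.5 + half,
       within = acc >= 0.5 - half && acc <= 0.5 + half, n1 = n1, n2 = n2)
}
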