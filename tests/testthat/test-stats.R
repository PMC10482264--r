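test_that("exact binomial test matches the enumeration oracle for all
           n <= 12", {
  for (n in c(3, 5, 8, 12)) {
    for (p0 in c(0.3, 0.5, 2 / 3)) {
      for (k in 0:n) {
        expect_equal(binom_test_two_sided(k, n, p0)$p_value,
                     binom_oracle(k, n, p0), tolerance = 1e-10,
                     label = sprintf("k=%d n=%d p0=%g", k, n, p0))
      }
    }
  }
})

test_that("exact binomial test agrees with the reference implementation", {
  set.seed(3)
  for (rep in 1:25) {
    n <- sample(5:500, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.05, 0.95)
    expect_equal(binom_test_two_sided(k, n, p0)$p_value,
                 stats::binom.test(k, n, p0)$p.value, tolerance = 1e-9)
  }
  # symmetric mode gives p = 1
  expect_equal(binom_test_two_sided(5, 10, 0.5)$p_value, 1)
  expect_error(binom_test_two_sided(11, 10), "<=")
  expect_error(binom_test_two_sided(1, 10, 0), "between")
})

test_that("Pearson chi-squared matches direct arithmetic and the reference
           implementation", {
  set.seed(4)
  for (rep in 1:25) {
    O <- matrix(rpois(4, 20) + 1, 2, 2)
    # independent hand computation
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    stat_hand <- sum((O - E)^2 / E)
    res <- chisq_contingency(O)
    expect_equal(res$statistic, stat_hand, tolerance = 1e-10)
    expect_equal(res$statistic,
                 suppressWarnings(stats::chisq.test(O, correct = FALSE))$statistic[[1]],
                 tolerance = 1e-10)
    expect_equal(res$df, 1L)
  }
})

test_that("chi-squared is permutation invariant and zero on proportional
           rows", {
  set.seed(5)
  O <- matrix(rpois(12, 15) + 1, 6, 2)
  base <- chisq_contingency(O)$statistic
  for (rep in 1:10) {
    Op <- O[sample(6), sample(2)]
    expect_equal(chisq_contingency(Op)$statistic, base, tolerance = 1e-10)
  }
  prop <- outer(c(1, 2, 3), c(10, 20))
  expect_equal(chisq_contingency(prop)$statistic, 0, tolerance = 1e-12)
  expect_error(chisq_contingency(matrix(c(0, 0, 3, 4), 2, 2)), "margin")
  expect_error(chisq_contingency(matrix(1:3, 3, 1)), "2 x 2")
})

test_that("windowed criterion finds the first qualifying window within a
           session", {
  # perfect log: met at trial 20 (needs >= 16 of 20)
  expect_equal(windowed_criterion(make_log(rep(TRUE, 30))), 20L)
  # alternating correct/incorrect never reaches 80%
  expect_true(is.na(windowed_criterion(make_log(rep(c(TRUE, FALSE), 30)))))
  # crafted log whose first qualifying window ends at trial 37
  correct <- c(rep(FALSE, 21), rep(TRUE, 16))
  expect_equal(windowed_criterion(make_log(correct)), 37L)
  # sessions are never straddled
  half <- make_log(rep(TRUE, 24), session = rep(1:2, each = 12))
  expect_true(is.na(windowed_criterion(half)))
  full <- make_log(rep(TRUE, 44), session = rep(1:2, c(12, 32)))
  expect_equal(windowed_criterion(full), 32L)  # 20th trial of session 2
})

test_that("block performance aggregates exactly and flags partial blocks", {
  log <- make_log(rep(TRUE, 120), trial_type = rep(c("AA", "AB"), 60))
  bp <- block_performance(log)
  expect_true(all(bp$proportion_correct == 1))
  # 60 AB of which 30 correct
  log2 <- make_log(c(rep(c(TRUE, FALSE), 30), rep(TRUE, 60)),
                   trial_type = c(rep("AB", 60), rep("BB", 60)))
  bp2 <- block_performance(log2)
  expect_equal(bp2$proportion_correct[bp2$trial_type == "AB"], 0.5)
  # re-aggregation reproduces overall accuracy exactly
  set.seed(6)
  log3 <- make_log(runif(300) < 0.6,
                   trial_type = sample(c("AA", "AB", "BA", "BB"), 300,
                                       replace = TRUE))
  bp3 <- block_performance(log3)
  overall <- bp3[bp3$trial_type == "all", ]
  expect_equal(sum(overall$k) / sum(overall$n), mean(log3$correct))
  # per-type counts agree with an independent groupby
  types <- bp3[bp3$trial_type != "all", ]
  expect_equal(sum(types$k), sum(log3$correct))
  ref <- tapply(log3$correct, log3$trial_type, sum)
  got <- tapply(types$k, types$trial_type, sum)
  expect_equal(unname(got[names(ref)]), unname(ref))
  # partial final block flagged with its own n
  expect_true(any(bp3$partial) == (300 %% 120 != 0))
  expect_equal(sum(bp3$n[bp3$trial_type == "all" & bp3$partial]), 300 %% 120)
  expect_error(block_performance(make_log(TRUE)[0, ]), "non-empty")
})

test_that("probe tables classify responses and count matching choices", {
  # an agent that always picks the second sample
  log <- reference_probe_log("kanzi")
  log$response <- log$sample_second_id
  pt <- probe_tables(log)
  expect_true(all(pt$table[, 1] == 0))
  expect_true(all(pt$table[, 2] == 20))
  expect_equal(pt$matching_count, pt$probe_total)
  # random agent at scale: about half of probe choices match a sample
  sched <- schedule_probe_phase(reps_per_condition = 100, seed = 12)
  rl <- run_task(random_agent(), sched, seed = 13)
  pr <- probe_tables(rl)
  expect_equal(pr$probe_total, 600)
  expect_lt(abs(pr$matching_count / pr$probe_total - 0.5), 0.07)
  expect_error(probe_tables(make_log(TRUE)), "no probe")
})

test_that("per-delay summaries report exact proportions, Wilson CIs and
           binomial p-values", {
  sched <- schedule_delayed_mts(40, seed = 14)
  log <- run_task(random_agent(), sched, seed = 15)
  log$correct <- TRUE                      # all-correct at every delay
  dp <- delay_performance(log)
  expect_true(all(dp$proportion_correct == 1))
  expect_equal(dp$p_value, 2 * 0.5^dp$n, tolerance = 1e-12)
  # exactly half correct: p ~ 1
  expect_gt(binom_test_two_sided(250, 500, 0.5)$p_value, 0.9)
  # Wilson interval is inside [0, 1] and contains the point estimate
  expect_true(all(dp$ci_lower <= dp$proportion_correct &
                    dp$proportion_correct <= dp$ci_upper))
})

test_that("per-delay proportions recover generating accuracies with
           nominal Wilson coverage", {
  truth <- c(`0` = 0.85, `2` = 0.70, `5` = 0.58, `10` = 0.55)
  set.seed(16)
  hits <- 0L; total <- 0L
  for (rep in 1:100) {
    k <- rbinom(4, 500, truth)
    for (j in 1:4) {
      ci <- wilson_ci(k[j], 500)
      hits <- hits + (truth[j] >= ci["lower"] && truth[j] <= ci["upper"])
      total <- total + 1L
    }
  }
  expect_gte(hits / total, 0.93)
})

test_that("balanced discrimination accuracy is chance-proof against side
           bias", {
  # a pure left-presser: high AB accuracy, zero BA accuracy, balanced 0.5
  tt <- rep(c("AB", "BA"), c(90, 30))
  log <- make_log(tt == "AB", trial_type = tt, response = "left")
  d <- discrimination_accuracy(log)
  expect_equal(d$balanced_accuracy, 0.5)
  expect_true(d$within)
  expect_error(discrimination_accuracy(make_log(TRUE, trial_type = "AA")),
               "lacks")
})
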