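test_that("vectorised probe likelihood equals the model prediction", {
  conds <- probe_conditions()
  for (g in c(0.6, 1, 1.8)) for (lam in c(0.1, 0.8)) for (b in c(1, 4)) {
    tp <- trace_params(gain = g, decay = lam, noise_sd = 0,
                       temperature = b, lapse = 0.05)
    p_ref <- vapply(seq_len(6), function(i)
      probe_prediction(conds$d_first[i], 0.3, conds$d_second[i],
                       params = tp), numeric(1))
    p_vec <- seqtrace:::probe_pred_vec(conds$d_first, conds$d_second, 0.3,
                                       g, lam, b, 0.05)
    expect_equal(p_vec, p_ref, tolerance = 1e-12)
  }
})

test_that("retention fit recovers generating parameters on dense data", {
  rp <- retention_params(0.8, 0.2)
  delays <- c(0, 2, 5, 10)
  n <- rep(1e4, 4)
  set.seed(31)
  k <- rbinom(4, n, retention_curve(delays, rp))
  fit <- fit_retention(delays, k, n)
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)[["asymptote"]] - 0.8), 0.05)
  expect_lt(abs(coef(fit)[["decay_rate"]] - 0.2), 0.05)
  # fitted curve respects [chance, 1] everywhere
  expect_true(all(predict(fit, seq(0, 100, by = 1)) >= 0.5 - 1e-9))
  expect_true(all(predict(fit, seq(0, 100, by = 1)) <= 1 + 1e-9))
  # methods behave
  expect_s3_class(fit, "retention_fit")
  expect_length(residuals(fit), 4)
  expect_equal(attr(logLik(fit), "nobs"), sum(n))
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sim, 2)
})

test_that("retention fit flags chance-level data as flat and keeps the
           amplitude at zero", {
  fit <- fit_retention(c(0, 2, 5, 10), rep(2500, 4), rep(5000, 4))
  expect_true("flat_likelihood" %in% fit$diagnostics)
  expect_lt(coef(fit)[["asymptote"]], 0.05)
  expect_true("decay_rate_unidentified" %in% fit$diagnostics)
  expect_error(fit_retention(0, 10, 20), "unidentifiable|distinct")
  expect_error(fit_retention(c(0, 5), c(30, 5), c(20, 20)), "k <= n")
})

test_that("trace-model probe fit handles uniform counts, recovers
           parameters, and is deterministic", {
  # uniform 10/10 rows: chance-level, flat likelihood, null not beaten
  uni <- matrix(10, 6, 2)
  f0 <- fit_trace_probes(uni)
  expect_true("flat_likelihood" %in% f0$diagnostics)
  lr <- lr_test(f0, fit_probe_null(uni), df = 2)
  expect_gt(lr$p_value, 0.05)
  # recovery at large reps
  tp <- trace_params(gain = 1, decay = 0.7, noise_sd = 0, temperature = 3,
                     lapse = 0)
  conds <- probe_conditions()
  p <- vapply(seq_len(6), function(i)
    probe_prediction(conds$d_first[i], 0.3, conds$d_second[i], params = tp),
    numeric(1))
  set.seed(32)
  k <- rbinom(6, 5000, p)
  fit <- fit_trace_probes(cbind(k, 5000 - k))
  expect_lt(abs(coef(fit)[["decay"]] - 0.7), 0.1)
  expect_lt(abs(coef(fit)[["temperature"]] - 3), 0.3)
  # profile CIs bracket the estimates
  expect_true(all(fit$profile_ci[, "lower"] <= coef(fit) + 1e-6))
  expect_true(all(fit$profile_ci[, "upper"] >= coef(fit) - 1e-6))
  expect_error(fit_trace_probes(uni[1:3, ]), "rows")
  # predict() at the fitted parameters reproduces the model probabilities
  expect_equal(predict(fit), seqtrace:::probe_pred_vec(
    conds$d_first, conds$d_second, 0.3, 1, coef(fit)[["decay"]],
    coef(fit)[["temperature"]], 0), tolerance = 1e-9)
})

test_that("likelihood-ratio test behaves at its anchors", {
  tab <- matrix(c(12, 8, 9, 11, 10, 10), 3, 2)
  f <- fit_probe_null(tab, "equal_choice")
  expect_equal(lr_test(f, f, df = 1)$statistic, 0)
  expect_equal(lr_test(f, f, df = 1)$p_value, 1)
  # df = 1, deviance 3.841 -> p ~ 0.05
  p <- stats::pchisq(3.841, 1, lower.tail = FALSE)
  expect_equal(p, 0.05, tolerance = 0.001)
  # a 'full' model markedly worse than its null is an optimization failure
  expect_error(lr_test(structure(list(log_likelihood = -10, n_obs = 10),
                                 class = "seqtrace_fit"),
                       structure(list(log_likelihood = -5, n_obs = 10),
                                 class = "seqtrace_fit"), df = 1),
               "negative deviance")
  # nested orderings hold for the reference fits
  set.seed(33)
  O <- matrix(rpois(12, 12) + 1, 6, 2)
  lls <- c(chance = fit_probe_null(O, "chance")$log_likelihood,
           common = fit_probe_null(O, "equal_choice")$log_likelihood,
           sat = fit_probe_null(O, "saturated")$log_likelihood)
  expect_true(lls["common"] >= lls["chance"] - 1e-8)
  expect_true(lls["sat"] >= lls["common"] - 1e-8)
})

test_that("fitted models never fall below their nested null", {
  set.seed(34)
  for (rep in 1:5) {
    k <- rbinom(6, 40, runif(1, 0.3, 0.7))
    tab <- cbind(k, 40 - k)
    fit <- fit_trace_probes(tab, profile = FALSE)
    expect_gte(fit$log_likelihood,
               fit_probe_null(tab, "chance")$log_likelihood - 1e-8)
  }
})

test_that("recovery studies are seed-deterministic and sharpen with data", {
  rs1 <- recovery_study(retention_params(0.7, 0.25),
                        list(model = "retention", delays = c(0, 2, 5, 10),
                             n_per_delay = 200), reps = 10, seed = 35)
  rs2 <- recovery_study(retention_params(0.7, 0.25),
                        list(model = "retention", delays = c(0, 2, 5, 10),
                             n_per_delay = 200), reps = 10, seed = 35)
  expect_identical(rs1$per_parameter, rs2$per_parameter)
  expect_error(recovery_study(retention_params(0.7, 0.25),
                              list(model = "retention",
                                   delays = c(0, 2, 5, 10),
                                   n_per_delay = 200), reps = 1, seed = 1),
               ">=")
  # RMSE of the forgetting rate decreases as per-delay n grows
  rmse <- vapply(c(20, 200, 2000), function(n) {
    rs <- recovery_study(retention_params(0.7, 0.25),
                         list(model = "retention", delays = c(0, 2, 5, 10),
                              n_per_delay = n), reps = 30, seed = 36)
    rs$per_parameter$rmse[rs$per_parameter$parameter == "decay_rate"]
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("confidence intervals cover a zero forgetting rate", {
  rs <- recovery_study(retention_params(0.3, 0),
                       list(model = "retention", delays = c(0, 2, 5, 10),
                            n_per_delay = 1000), reps = 50, seed = 37)
  cov <- rs$per_parameter$coverage[rs$per_parameter$parameter == "decay_rate"]
  expect_gte(cov, 0.90)
})
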