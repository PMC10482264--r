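test_that("encoding intensity follows the saturating law and its limits", {
  p <- trace_params(gain = 1)
  expect_equal(encode_intensity(1, p), 1 - exp(-1), tolerance = 1e-12)
  # vanishing exposure leaves no trace; long exposure saturates at 1
  expect_lt(encode_intensity(1e-9, p), 1e-8)
  expect_equal(encode_intensity(1e6, p), 1, tolerance = 1e-12)
  # strictly increasing in duration, bounded by 1
  d <- seq(0.1, 10, by = 0.1)
  v <- encode_intensity(d, p)
  expect_true(all(diff(v) > 0))
  expect_true(all(v <= 1))
  # linear law option
  expect_equal(encode_intensity(2, trace_params(gain = 0.4,
                                                encoding = "linear")), 0.8)
  expect_error(encode_intensity(0, p), "positive")
  expect_error(encode_intensity(-1, p), "positive")
})

test_that("trace state decays, adds over presentations, and is zero for
           unseen stimuli", {
  p <- trace_params(gain = 1, decay = 0.5)
  ev <- stimulus_events(c("A", "B"), c(0, 1.3), c(1, 2.3))
  st <- trace_state(ev, 2.3, p)
  expect_equal(unname(st$intensities["A"]), (1 - exp(-1)) * exp(-0.5 * 1.3),
               tolerance = 1e-6)
  expect_equal(unname(st$intensities["B"]), 1 - exp(-1), tolerance = 1e-6)
  # recency: equal durations, positive decay -> second beats first
  expect_gt(st$intensities["B"], st$intensities["A"])
  # no decay: state independent of query time
  p0 <- trace_params(gain = 1, decay = 0)
  expect_equal(trace_state(ev, 2.3, p0)$intensities,
               trace_state(ev, 100, p0)$intensities)
  # querying before the last offset is invalid
  expect_error(trace_state(ev, 2.0, p), "precedes")
  # unseen stimuli have intensity exactly 0 in choice
  st1 <- trace_state(ev, 3, p)
  pr <- choice_probabilities(st1, c("A", "B", "C"), trace_params(lapse = 0))
  expect_true(pr[["C"]] < pr[["A"]])
})

test_that("trace intensities decay monotonically and add over disjoint
           event sets", {
  set.seed(42)
  p <- trace_params(gain = 1.3, decay = 0.4)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    dur <- runif(n, 0.2, 2)
    gaps <- runif(n, 0, 1)
    onset <- cumsum(c(0, (dur + gaps)[-n]))
    ids <- sample(c("A", "B", "C"), n, replace = TRUE)
    ev <- stimulus_events(ids, onset, onset + dur)
    t1 <- max(ev$offset) + runif(1, 0, 2)
    t2 <- t1 + runif(1, 0.1, 3)
    s1 <- trace_state(ev, t1, p)$intensities
    s2 <- trace_state(ev, t2, p)$intensities
    expect_true(all(s2 <= s1))
    expect_true(all(s2 >= 0))
    # additivity: split events into two disjoint sets
    if (n >= 3) {
      take <- seq_len(n) <= n %/% 2
      sa <- trace_state(ev[take, ], t1, p)$intensities
      sb <- trace_state(ev[!take, ], t1, p)$intensities
      all_ids <- union(names(sa), names(sb))
      get0 <- function(s, id) if (id %in% names(s)) s[[id]] else 0
      for (id in all_ids)
        expect_equal(get0(s1, id), get0(sa, id) + get0(sb, id),
                     tolerance = 1e-12)
    }
  }
})

test_that("choice probabilities: symmetry, degenerate parameters, logistic
           value, normalisation and permutation equivariance", {
  ev <- stimulus_events(c("A", "B"), c(0, 1.3), c(1, 2.3))
  # equal intensities -> uniform
  st_eq <- trace_state(stimulus_events(c("A", "B"), c(0, 1.5), c(1, 2.5)),
                       3, trace_params(decay = 0))
  pr <- choice_probabilities(st_eq, c("A", "B"), trace_params(decay = 0))
  expect_equal(unname(pr), c(0.5, 0.5), tolerance = 1e-12)
  # beta = 0 and eps = 1 are uniform regardless of the traces
  st <- trace_state(ev, 2.3, trace_params(decay = 0.5))
  expect_equal(unname(choice_probabilities(
    st, c("A", "B", "C"), trace_params(temperature = 0, lapse = 0))),
    rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(unname(choice_probabilities(
    st, c("A", "B", "C"), trace_params(lapse = 1))),
    rep(1 / 3, 3), tolerance = 1e-12)
  # two options, intensities (1, 0), beta = 4, eps = 0 -> logistic
  stx <- structure(list(intensities = c(X = 1), query_time = 5),
                   class = "trace_state")
  prx <- choice_probabilities(stx, c("X", "Y"),
                              trace_params(temperature = 4, lapse = 0))
  expect_equal(unname(prx[1]), 1 / (1 + exp(-4)), tolerance = 1e-9)
  # normalisation to 1e-12 and permutation equivariance, both rules
  set.seed(7)
  for (rule in c("softmax", "noisy_max")) {
    for (rep in 1:10) {
      ids <- c("A", "B", "C", "D")
      stc <- structure(list(intensities = setNames(runif(4), ids),
                            query_time = 10), class = "trace_state")
      pp <- trace_params(temperature = runif(1, 0, 6),
                         noise_sd = runif(1, 0.05, 1),
                         lapse = runif(1, 0, 0.3))
      p1 <- choice_probabilities(stc, ids, pp, rule = rule)
      expect_equal(sum(p1), 1, tolerance = 1e-12)
      perm <- sample(ids)
      p2 <- choice_probabilities(stc, perm, pp, rule = rule)
      expect_equal(p2[ids], p1[ids], tolerance = 1e-9)
    }
  }
  expect_error(choice_probabilities(st, character(0), trace_params()),
               "non-empty")
})

test_that("noisy-max probabilities match a Monte Carlo oracle", {
  st <- structure(list(intensities = c(A = 0.8, B = 0.5), query_time = 3),
                  class = "trace_state")
  pp <- trace_params(noise_sd = 0.4, lapse = 0)
  p <- choice_probabilities(st, c("A", "B", "C"), pp, rule = "noisy_max")
  set.seed(123)
  draws <- replicate(200000, {
    z <- c(0.8, 0.5, 0) + rnorm(3, 0, 0.4)
    which.max(z)
  })
  mc <- tabulate(draws, 3) / length(draws)
  expect_equal(unname(p), mc, tolerance = 0.01)
})

test_that("probe predictions show recency, symmetry at zero decay, and
           duration monotonicity", {
  p <- trace_params(gain = 1, decay = 0.7, temperature = 3, lapse = 0)
  # recency: equal durations, positive decay
  expect_lt(probe_prediction(1, 0.3, 1, params = p), 0.5)
  # zero decay, equal durations: symmetric traces
  expect_equal(probe_prediction(1, 0.3, 1,
                                params = trace_params(decay = 0, lapse = 0)),
               0.5, tolerance = 1e-12)
  # non-decreasing in d_first over a grid of parameter settings
  for (g in c(0.5, 1, 2)) for (lam in c(0.1, 0.5, 1.5)) {
    pp <- trace_params(gain = g, decay = lam, temperature = 4, lapse = 0.05)
    v <- vapply(seq(0.2, 5, by = 0.2), function(d1)
      probe_prediction(d1, 0.3, 1, params = pp), numeric(1))
    expect_true(all(diff(v) >= -1e-12))
  }
  # fixed first duration: P(first) strictly decreasing in the second
  # duration across the three 1-s-first probe conditions
  for (g in c(0.5, 1, 2)) for (lam in c(0.1, 0.5, 1.5)) {
    pp <- trace_params(gain = g, decay = lam, temperature = 4, lapse = 0.05)
    v <- vapply(c(0.5, 1.5, 4.5), function(d2)
      probe_prediction(1, 0.3, d2, params = pp), numeric(1))
    expect_true(all(diff(v) < 0))
  }
})

test_that("retention curve has the right anchors and never leaves
           [chance, 1]", {
  rp <- retention_params(0.8, 0.2, 0.5)
  expect_equal(retention_curve(5, rp), 0.5 + 0.5 * 0.8 * exp(-1),
               tolerance = 1e-12)
  expect_equal(retention_curve(0, rp), 0.5 + 0.5 * 0.8)
  # no memory and no forgetting degenerate cases
  expect_equal(retention_curve(c(0, 3, 9), retention_params(0, 1, 0.5)),
               rep(0.5, 3))
  expect_equal(retention_curve(c(0, 3, 9), retention_params(0.6, 0, 0.5)),
               rep(0.5 + 0.5 * 0.6, 3))
  # bounds over a parameter grid
  for (a in c(0, 0.5, 1)) for (l in c(0, 0.3, 3)) for (c0 in c(0.25, 0.5)) {
    v <- retention_curve(seq(0, 50, by = 0.5), retention_params(a, l, c0))
    expect_true(all(v >= c0 - 1e-12 & v <= 1 + 1e-12))
  }
  expect_error(retention_curve(-1, rp), "non-negative")
})

test_that("parameter objects validate bounds and round-trip through JSON", {
  expect_error(trace_params(gain = 0), ">")
  expect_error(trace_params(decay = -1), ">=")
  expect_error(trace_params(lapse = 1.5), "<=")
  expect_error(retention_params(chance = 1), "between")
  tp <- trace_params(gain = 1.7, decay = 0.12, noise_sd = 0.9,
                     temperature = 2.5, lapse = 0.07)
  tp2 <- params_from_json(params_to_json(tp))
  expect_equal(tp2, tp)
  rp <- retention_params(0.66, 0.31, 0.25)
  f <- tempfile(fileext = ".json")
  params_to_json(rp, f)
  expect_equal(params_from_json(f), rp)
  unlink(f)
})
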