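test_that("extract_perievent aligns trials and drops incomplete coverage", {
  tr <- make_trace(rep(2.5, 200))  # 20 s at 10 Hz
  pem <- extract_perievent(tr, c(5, 10, 15), pre_s = 2, post_s = 2)
  expect_equal(dim(pem$values), c(3, 41))
  expect_true(all(pem$values == 2.5))
  expect_equal(pem$n_dropped, 0)

  # a step at the event time appears as a step at rel time 0
  step_tr <- make_trace(c(rep(0, 100), rep(1, 100)))
  pem2 <- extract_perievent(step_tr, 10, pre_s = 2, post_s = 2)
  v <- pem2$values[1, ]
  expect_true(all(v[pem2$rel_time_s < -1e-9] == 0))
  expect_true(all(v[pem2$rel_time_s >= 0] == 1))

  # an event 1 s from session start with pre = 2 is dropped and counted
  pem3 <- extract_perievent(tr, c(1, 10), pre_s = 2, post_s = 2)
  expect_equal(pem3$n_dropped, 1)
  expect_equal(nrow(pem3$values), 1)
  expect_error(extract_perievent(tr, 1, pre_s = 2, post_s = 2),
               class = "ff_empty_error")
})

test_that("trial_mean gives pointwise mean and sd/sqrt(n)", {
  tr <- make_trace(rep(1, 100))
  pem <- extract_perievent(tr, 5, pre_s = 1, post_s = 1)
  tm1 <- trial_mean(pem)
  expect_equal(tm1$n, 1)
  expect_equal(tm1$mean, pem$values[1, ])
  expect_true(all(tm1$sem == 0))
  expect_true(isTRUE(attr(tm1$sem, "single_trial")))

  # two constant trials at +1 / -1: mean 0, sem = sd/sqrt(n) = sqrt(2)/sqrt(2)
  pem2 <- list(rel_time_s = seq(-1, 1, 0.1),
               values = rbind(rep(1, 21), rep(-1, 21)),
               event_times_s = c(1, 2), n_dropped = 0, source_label = "x")
  class(pem2) <- "perievent_matrix"
  tm2 <- trial_mean(pem2)
  expect_equal(tm2$mean, rep(0, 21))
  expect_equal(tm2$sem, rep(1, 21), tolerance = 1e-12)

  # Monte-Carlo: 100 unit-noise trials -> sem within 20% of 0.1 pointwise
  set.seed(1)
  pem3 <- list(rel_time_s = seq(-1, 1, 0.1),
               values = matrix(rnorm(100 * 21), 100, 21),
               event_times_s = 1:100, n_dropped = 0, source_label = "x")
  class(pem3) <- "perievent_matrix"
  tm3 <- trial_mean(pem3)
  expect_true(all(abs(tm3$sem - 0.1) < 0.02))
})

test_that("window_table returns the exact named windows for all four tests", {
  expect_equal(window_table("airpuff"),
               structure(list(baseline = c(-2, -1), airpuff = c(0, 1.5)),
                         test_name = "airpuff",
                         class = c("window_spec", "list")))
  expect_equal(window_table("consumption")[["onset"]], c(-0.5, 1))
  expect_equal(window_table("consumption")[["drinking"]], c(2, 4))
  expect_equal(window_table("mobility"),
               structure(list(immobile = c(-3, -1), pre_onset = c(-1, 0),
                              onset = c(0, 1), mobility = c(1, 3)),
                         test_name = "mobility",
                         class = c("window_spec", "list")))
  expect_equal(window_table("avoidance")[["CS"]], c(0, 8))
  expect_equal(window_table("avoidance")[["crossed"]], c(8, 11))
  expect_equal(window_table("avoidance")[["baseline"]], c(-2, -1))
  expect_error(window_table("unknown"), class = "ff_key_error")
})

test_that("normalized AUC has the mean-value property", {
  # constant c over any window -> c
  tr <- make_trace(rep(2.0, 300))
  pem <- extract_perievent(tr, 15, pre_s = 5, post_s = 5)
  for (test in c("airpuff", "consumption", "mobility")) {
    for (w in window_table(test))
      expect_equal(perievent_auc(pem, w)$mean, 2.0, tolerance = 1e-12)
  }
  # linear ramp 0 -> 1 across a window integrates to 1/2
  ramp <- list(rel_time_s = seq(0, 1, 0.01), mean = seq(0, 1, 0.01))
  expect_equal(perievent_auc(ramp, c(0, 1))$mean, 0.5, tolerance = 1e-12)

  expect_error(perievent_auc(pem, c(-10, 0)), class = "ff_range_error")
  expect_error(perievent_auc(pem, c(1, 1)), class = "ff_param_error")
})

test_that("trapezoidal AUC matches a refined Riemann oracle and is linear", {
  set.seed(9)
  n <- 101
  t <- seq(-5, 5, length.out = n)
  y <- as.numeric(stats::filter(rnorm(n), rep(1 / 5, 5), circular = TRUE))
  pem <- list(rel_time_s = t, mean = y)
  w <- c(-2, 1.5)
  got <- perievent_auc(pem, w)$mean
  # Riemann midpoint sum on a 10x refined grid of the same piecewise-linear curve
  tf <- seq(w[1], w[2], length.out = 10 * n)
  yf <- approx(t, y, xout = tf)$y
  mid <- (yf[-1] + yf[-length(yf)]) / 2
  oracle <- sum(mid * diff(tf)) / diff(w)
  expect_equal(got, oracle, tolerance = 1e-3)

  # linearity in the input
  y2 <- rnorm(n)
  a1 <- perievent_auc(list(rel_time_s = t, mean = y), w)$mean
  a2 <- perievent_auc(list(rel_time_s = t, mean = y2), w)$mean
  a12 <- perievent_auc(list(rel_time_s = t, mean = 2 * y + 3 * y2), w)$mean
  expect_equal(a12, 2 * a1 + 3 * a2, tolerance = 1e-9)
})

test_that("peri-event averaging locks onto planted mobility onsets", {
  cfg <- small_config(duration_s = 300, coupling_lag_s = 0, noise_sd = 0.5,
                      artifact_amp = 0, transient_rate_hz = 0)
  ses <- generate_session(cfg)
  clean <- ses$ground_truth$clean_transient_trace
  pem <- extract_perievent(clean, ses$events$mobility_onset,
                           pre_s = 3, post_s = 3)
  tm <- trial_mean(pem)
  # pre-onset plateau low, post-onset plateau high
  expect_lt(mean(tm$mean[tm$rel_time_s < -0.5]), 0.2 * max(tm$mean))
  expect_gt(mean(tm$mean[tm$rel_time_s > 1]), 0.8 * max(tm$mean))
  # the half-rise crossing sits within one ramp of the event time
  half <- (min(tm$mean) + max(tm$mean)) / 2
  cross <- tm$rel_time_s[which(tm$mean >= half)[1]]
  expect_gte(cross, -0.1)
  expect_lte(cross, 0.4)
})

test_that("auc_table emits one row per trial and window", {
  tr <- make_trace(rnorm(400))
  pem <- extract_perievent(tr, c(10, 20, 30), pre_s = 5, post_s = 5)
  tab <- auc_table(pem, "mobility")
  expect_equal(nrow(tab), 3 * 4)
  expect_setequal(unique(tab$window),
                  c("immobile", "pre_onset", "onset", "mobility"))
})
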