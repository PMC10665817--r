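test_that("moving-average smoothing preserves DC, length and phase", {
  const <- make_trace(rep(3.5, 50))
  expect_equal(smooth_trace(const)$value, rep(3.5, 50))
  expect_equal(smooth_trace(const)$time_s, const$time_s)

  # unit impulse through a width-5 kernel: five samples of 0.2
  imp <- make_trace(c(rep(0, 20), 1, rep(0, 20)))
  sm <- smooth_trace(imp, preprocess_params(smooth_window_s = 0.5))
  expect_equal(sm$value[19:23], rep(0.2, 5))
  expect_equal(sum(sm$value), 1)  # mass conserved

  expect_error(smooth_trace(make_trace(c(1, 2)),
                            preprocess_params(smooth_window_s = 1)),
               class = "ff_data_error")
})

test_that("a 4 Hz sinusoid is strongly attenuated by a 0.5-s moving average", {
  # the width-5 boxcar at 10 Hz has |H(4 Hz)| = |sin(2*pi)| / (5 sin(0.4*pi)) = 0
  t <- (0:499) / 10
  tr <- make_trace(sin(2 * pi * 4 * t))
  sm <- smooth_trace(tr, preprocess_params(smooth_window_s = 0.5))
  interior <- sm$value[50:450]
  expect_lt(max(abs(interior)), 0.25)
})

test_that("the zero-phase low-pass alternative attenuates without phase shift", {
  t <- (0:999) / 10
  slow <- sin(2 * pi * 0.2 * t)
  fast <- sin(2 * pi * 4 * t)
  tr <- make_trace(slow + fast)
  sm <- smooth_trace(tr, preprocess_params(smooth_window_s = NULL,
                                           lowpass_cutoff_hz = 1))
  interior <- 100:900
  expect_lt(max(abs(sm$value[interior] - slow[interior])), 0.1)
  expect_error(preprocess_params(smooth_window_s = 1, lowpass_cutoff_hz = 1),
               class = "ff_param_error")
  expect_error(preprocess_params(smooth_window_s = NULL,
                                 lowpass_cutoff_hz = NULL),
               class = "ff_param_error")
})

test_that("airPLS reproduces trivially flat and linear baselines", {
  expect_equal(as.numeric(airpls_baseline(rep(2, 50), lambda = 1e4)),
               rep(2, 50), tolerance = 1e-6)
  # a noiseless straight line is its own baseline (second differences vanish)
  line <- seq(0, 10, length.out = 200)
  b <- airpls_baseline(line, lambda = 1e4)
  expect_lt(max(abs(as.numeric(b) - line)), 1e-3 * diff(range(line)))
  expect_error(airpls_baseline(c(1, NA, 3)), class = "ff_data_error")
  expect_error(airpls_baseline(c(1, 2)), class = "ff_data_error")
})

test_that("airPLS matches the uniform-weight Whittaker solve on peak-free input", {
  # smooth, peak-free: the reweighting never departs far from uniform
  set.seed(7)
  n <- 400
  t <- seq(0, 1, length.out = n)
  y <- 5 + 3 * t + 0.5 * sin(2 * pi * t)
  lam <- 1e4
  oracle <- whittaker_uniform_oracle(y, lam)
  b <- airpls_baseline(y, lambda = lam)
  expect_lt(max(abs(as.numeric(b) - oracle)), 1e-3 * diff(range(y)))
  # the negative-residual criterion decreases monotonically
  path <- attr(b, "criterion_path")
  expect_true(all(diff(path) <= 1e-12))
})

test_that("airPLS passes under an added positive peak", {
  n <- 600
  line <- seq(1, 2, length.out = n)
  peak_height <- 10 * diff(range(line))
  y <- line + peak_height * exp(-((seq_len(n) - 300)^2) / (2 * 15^2))
  b <- as.numeric(airpls_baseline(y, lambda = 1e6, max_iter = 50))
  # the baseline ignores the peak at its center ...
  expect_lt(abs(b[300] - line[300]), 0.05 * peak_height)
  # ... and never exceeds the global maximum of the input
  expect_lte(max(b), max(y) + 1e-9)
})

test_that("standardize yields exact zero mean and unit sd, with degenerate guard", {
  z <- standardize(c(1, 2, 3))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_false(attr(z, "degenerate"))

  zc <- standardize(rep(4, 10))
  expect_equal(as.numeric(zc), rep(0, 10))
  expect_true(attr(zc, "degenerate"))

  # affine invariance (sign-preserving)
  y <- rnorm(100)
  expect_equal(as.numeric(standardize(3 * y + 7)),
               as.numeric(standardize(y)), tolerance = 1e-9)
})

test_that("fit_reference matches a constrained numerical oracle", {
  set.seed(11)
  n <- 2000
  ref <- as.numeric(standardize(rnorm(n)))
  sig <- 0.7 * ref + rnorm(n, 0, 0.3)
  alpha <- 1e-3
  fit <- fit_reference(ref, sig, alpha)
  expect_true(abs(fit$slope_a - 0.7) < 0.05)

  # independent oracle: box-constrained numerical minimization of the same loss
  loss <- function(par) {
    a <- par[1]; b <- par[2]
    mean((sig - a * ref - b)^2) / 2 + alpha * abs(a)
  }
  o <- optim(c(0.5, 0), loss, method = "L-BFGS-B",
             lower = c(0, -Inf), upper = c(Inf, Inf))
  expect_equal(fit$slope_a, o$par[1], tolerance = 1e-4)
  expect_equal(fit$intercept_b, o$par[2], tolerance = 1e-4)
  expect_equal(fit$fitted_reference, fit$slope_a * ref + fit$intercept_b)
})

test_that("fit_reference honors the non-negativity constraint and exactness", {
  x <- as.numeric(standardize(rnorm(500)))
  perfect <- fit_reference(x, x, l1_alpha = 0)
  expect_lt(abs(perfect$slope_a - 1), 1e-6)
  expect_lt(abs(perfect$intercept_b), 1e-6)

  anti <- fit_reference(x, -x, l1_alpha = 0)
  expect_identical(anti$slope_a, 0)

  expect_error(fit_reference(x, x[-1]), class = "ff_data_error")
})

test_that("compute_zdff recovers the clean calcium component", {
  cfg <- synth_config(duration_s = 600, seed = 1)
  ses <- generate_session(cfg)
  tr <- deinterleave(ses$recording)
  z <- compute_zdff(tr[["470"]]$Region0, tr[["415"]]$Region0)
  ct <- ses$ground_truth$clean_transient_trace
  idx <- gt_index(z, ct)
  expect_gte(cor(z$value, ct$value[idx]), 0.8)
})

test_that("correction shrinks artifact-only sessions toward zero", {
  cfg <- small_config(duration_s = 300, transient_rate_hz = 0,
                      coupling_amp = 0, noise_sd = 1.25)
  ses <- generate_session(cfg)
  tr <- deinterleave(ses$recording)
  z <- compute_zdff(tr[["470"]]$Region0, tr[["415"]]$Region0)
  z_raw <- standardize(tr[["470"]]$Region0$value)
  expect_lt(sd(z$value), 0.5 * sd(as.numeric(z_raw)))
})

test_that("self-subtraction gives identically zero zdF/F with no penalty", {
  ref <- make_trace(100 + rnorm(500))
  z <- compute_zdff(ref, ref, preprocess_params(l1_alpha = 0))
  expect_lt(max(abs(z$value)), 1e-6)
  # and the mean is intercept-free
  sig <- make_trace(100 + rnorm(500))
  z2 <- compute_zdff(sig, ref, preprocess_params(l1_alpha = 0))
  expect_lt(abs(mean(z2$value)), 1e-6)
})

test_that("zdF/F is invariant to affine rescaling of camera units", {
  cfg <- small_config(duration_s = 120)
  ses <- generate_session(cfg)
  tr <- deinterleave(ses$recording)
  sig <- tr[["470"]]$Region0; ref <- tr[["415"]]$Region0
  z1 <- compute_zdff(sig, ref)
  sig2 <- photometry_trace(sig$time_s, 2.5 * sig$value + 40,
                           channel = "470", rate_hz = 10)
  ref2 <- photometry_trace(ref$time_s, 0.5 * ref$value - 3,
                           channel = "415", rate_hz = 10)
  z2 <- compute_zdff(sig2, ref2)
  expect_equal(z1$value, z2$value, tolerance = 1e-6)
})

test_that("non-overlapping traces raise an alignment error", {
  a <- photometry_trace(0:99 / 10, rnorm(100), rate_hz = 10)
  b <- photometry_trace(20 + 0:99 / 10, rnorm(100), rate_hz = 10)
  expect_error(compute_zdff(a, b), class = "ff_alignment_error")
})
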