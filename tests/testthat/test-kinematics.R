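test_that("zero-phase Butterworth filter has the expected magnitude response", {
  # DC gain 1
  expect_equal(lowpass_filter(rep(2.5, 500), 240), rep(2.5, 500),
               tolerance = 1e-9)
  tt <- (0:4799) / 240
  core <- 1000:3800
  # 1 Hz passband: amplitude within 1%
  y1 <- lowpass_filter(sin(2 * pi * 1 * tt), 240)
  expect_equal(max(abs(y1[core])), 1, tolerance = 0.01)
  # 30 Hz stopband: residual near the squared single-pass magnitude
  # (1 + (30/12)^8)^-1 ~= 6.6e-4; the digital design is slightly steeper
  y30 <- lowpass_filter(sin(2 * pi * 30 * tt), 240)
  resid <- max(abs(y30[core]))
  expect_lt(resid, 1.2 * 6.6e-4)
  expect_gt(resid, 0.3 * 6.6e-4)
  # errors: unusable sampling rate or too-short series
  expect_error(lowpass_filter(rnorm(100), fs = 20), "twice the filter cutoff")
  expect_error(lowpass_filter(rnorm(10), fs = 240), "too short")
})

test_that("heel strikes on noiseless trials match ground truth within one frame", {
  errs <- event_errors(fixture_result(), fixture_trial())
  expect_equal(nrow(fixture_result()$events), nrow(fixture_trial()$truth$events))
  expect_lte(max(abs(errs$rhs)), 1)
  expect_lte(max(abs(errs$lhs)), 1)
  expect_lte(max(abs(errs$lto)), 1)
  expect_lte(max(abs(errs$rto)), 1)
  # constant-height trajectory: no events
  expect_length(detect_heel_strikes(rep(0.05, 5000), 240, 1.1), 0)
})

test_that("event detection stays within two frames at 1 mm marker noise", {
  errs <- event_errors(fixture_noisy_result(), fixture_noisy_trial())
  expect_lte(max(abs(unlist(errs))), 2)
  # stride count within boundary strides of the generator count
  expect_gte(nrow(fixture_noisy_result()$events),
             nrow(fixture_noisy_trial()$truth$events) - 2)
})

test_that("toe offs are found per heel-strike interval and events interleave", {
  ev <- fixture_result()$events
  expect_true(all(ev$rhs < ev$lto & ev$lto < ev$lhs & ev$lhs < ev$rto))
  expect_true(all(diff(ev$rhs) > 0))
  # exactly 2 heel strikes -> exactly 1 toe off
  trial <- fixture_trial()
  zf <- fixture_result()$filtered$l_toe[, 3]
  iv <- matrix(c(ev$rhs[5], ev$lhs[5]), 1)
  expect_length(detect_toe_offs(zf, trial$fs, iv), 1)
  expect_length(detect_toe_offs(zf, trial$fs, iv[0, , drop = FALSE]), 0)
})

test_that("COM estimate is the pelvis-marker mean and permutation invariant", {
  n <- 10
  traj <- cbind(x = rnorm(n), y = rnorm(n), z = rnorm(n))
  expect_equal(estimate_com(traj, traj, traj, traj), traj)
  sq <- function(x, y) cbind(x = rep(x, n), y = rep(y, n), z = rep(0, n))
  expect_equal(estimate_com(sq(1, 1), sq(1, -1), sq(-1, 1), sq(-1, -1)),
               sq(0, 0))
  m <- function(x) cbind(x = rep(x, 2), y = 0, z = 0)
  expect_equal(estimate_com(m(0.1), m(0.3), m(0.1), m(0.3))[1, "x"],
               c(x = 0.2))
  a <- cbind(rnorm(n), rnorm(n), rnorm(n)); b <- a + 1; c <- a - 2; d <- a * 2
  expect_equal(estimate_com(a, b, c, d), estimate_com(d, b, a, c))
  expect_error(estimate_com(a, b, c, NULL), "missing pelvis marker")
})

test_that("numerical differentiation matches analytic derivatives", {
  fs <- 240
  tt <- (0:2399) / fs
  expect_equal(com_velocity(tt * 1.0, fs), rep(1.0, 2400), tolerance = 1e-12)
  expect_equal(com_velocity(rep(3.3, 2400), fs), rep(0, 2400))
  v <- com_velocity(sin(2 * pi * tt), fs)
  interior <- 2:2399
  expect_lt(max(abs(v[interior] - 2 * pi * cos(2 * pi * tt[interior]))), 1e-3)
})
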