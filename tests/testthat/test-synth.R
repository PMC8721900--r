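test_that("belt profiles hit their targets and respect the acceleration limit", {
  t_grid <- seq(-0.1, 0.6, by = 1 / 2400)
  targets <- c("Stick0.4" = 0.6, "Stick0.2" = 0.8, "Slip0.2" = 1.2,
               "Slip0.4" = 1.4)
  for (cond in names(targets)) {
    spec <- perturbation_spec(cond)
    v <- make_belt_profile(spec, t_grid, onset = 0)
    ext <- if (targets[[cond]] > 1) max(v) else min(v)
    expect_equal(ext, targets[[cond]], tolerance = 1e-12)
    expect_true(all(v[t_grid < 0] == 1.0))
    expect_true(all(v[t_grid > 0.4] == 1.0))
    expect_lte(max(abs(diff(v))) * 2400, 12.5 + 1e-9)
  }
  # ramp time to target: |dv| / a
  v <- make_belt_profile(perturbation_spec("Slip0.4"), c(0.4 / 12.5), onset = 0)
  expect_equal(v, 1.4, tolerance = 1e-12)
  v <- make_belt_profile(perturbation_spec("Slip0.4"), c(0.4 / 12.5 - 1e-4), 0)
  expect_lt(v, 1.4)
  expect_error(perturbation_spec("Slip0.4", belt_accel = 1),
               "infeasible belt ramp")
  expect_error(make_belt_profile(perturbation_spec("M1"), t_grid),
               "stick/slip")
})

test_that("shift profiles are bang-bang limited, reach 1 cm, and return to neutral", {
  t_grid <- seq(0, 0.4, by = 1 / 4800)
  for (cond in c("M1", "L1")) {
    spec <- perturbation_spec(cond)
    p <- make_shift_profile(spec, t_grid, onset = 0)
    peak <- if (cond == "L1") max(p) else -min(p)
    expect_equal(peak, 0.01, tolerance = 1e-12)
    expect_equal(sign(p[which.max(abs(p))]), if (cond == "L1") 1 else -1)
    expect_equal(p[length(p)], 0, tolerance = 1e-12)
    acc <- diff(p, differences = 2) * 4800^2
    expect_lte(max(abs(acc)), 3.6 + 1e-6)
  }
  # minimum one-way travel time for a rest-to-rest bang-bang move:
  # t = 2 * sqrt(d / a); the peak is attained exactly then
  t1 <- 2 * sqrt(0.01 / 3.6)
  expect_equal(t1, 0.1054093, tolerance = 1e-6)
  spec <- perturbation_spec("L1")
  expect_equal(make_shift_profile(spec, t1, onset = 0), 0.01,
               tolerance = 1e-12)
  expect_lt(make_shift_profile(spec, t1 - 1e-3, onset = 0), 0.01)
  expect_error(perturbation_spec("L1", duration = 0.15),
               "infeasible platform shift")
})

test_that("catch schedule draws one catch per complete 5-stride batch", {
  s5 <- generate_schedule(5, seed = 1)
  expect_equal(sum(s5$labels == "catch"), 1L)
  for (seed in 1:10) {
    s <- generate_schedule(200, seed = seed)
    expect_equal(sum(s$labels == "catch"), 40L)
    per_batch <- tapply(s$labels == "catch",
                        rep(1:40, each = 5), sum)
    expect_true(all(per_batch == 1))
  }
  # remainder batch (< 5 strides) is all perturbed
  s7 <- generate_schedule(7, seed = 3)
  expect_equal(sum(s7$labels[1:5] == "catch"), 1L)
  expect_true(all(s7$labels[6:7] == "perturbed"))
  # determinism + RNG isolation
  expect_identical(generate_schedule(50, seed = 42)$labels,
                   generate_schedule(50, seed = 42)$labels)
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_schedule(50, seed = 1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("zero-response zero-noise trials are steady and periodic", {
  trial <- fixture_trial()
  res <- fixture_result()
  lhs_rows <- res$stability[res$stability$event == "lhs", ]
  for (col in c("bos_ap", "bos_ml", "xcom_ap", "xcom_ml", "mos_ap", "mos_ml"))
    expect_lt(diff(range(lhs_rows[[col]])), 1e-8)
  # strict marker periodicity one stride apart (stride period = 264 frames)
  Tf <- round(trial$fs / trial$gait$cadence)
  idx <- 2000:3000
  for (m in c("l_heel", "r_toe", "LASI"))
    expect_equal(trial$markers[[m]][idx, ], trial$markers[[m]][idx + Tf, ],
                 tolerance = 1e-9)
  # treadmill state flat for condition "none"
  expect_true(all(trial$treadmill$belt_right_mps == 1.0))
  expect_true(all(trial$treadmill$platform_y_m == 0))
  expect_true(all(trial$treadmill$belt_left_mps == 1.0))
})

test_that("trial generation is deterministic and validates its configuration", {
  a <- generate_trial(gait_config(noise_sd = 0.002), perturbation_spec("M1"),
                      blocks = short_blocks(13, 10, 0), seed = 5)
  b <- generate_trial(gait_config(noise_sd = 0.002), perturbation_spec("M1"),
                      blocks = short_blocks(13, 10, 0), seed = 5)
  expect_identical(a$markers, b$markers)
  expect_identical(a$truth$labels, b$truth$labels)
  expect_error(gait_config(step_length = -0.1), "step_length")
  expect_error(gait_config(walking_speed = 0), "walking_speed")
  expect_error(gait_config(noise_sd = -1), "noise_sd")
  expect_error(gait_config(cadence = 2), "inconsistent gait geometry")
  expect_error(generate_trial(gait_config(),
                              perturbation_spec("M1", baseline_speed = 1.2)),
               "baseline_speed")
})

test_that("perturbation insertion follows the mid-stance trigger schedule", {
  trial <- generate_trial(gait_config(noise_sd = 0),
                          perturbation_spec("Slip0.4"),
                          blocks = short_blocks(), seed = 21)
  truth <- trial$truth
  pert <- which(truth$labels == "perturbed")
  expect_true(all(!is.na(truth$onsets[pert])))
  expect_true(all(is.na(truth$onsets[truth$labels == "catch"])))
  ev <- truth$events
  # onset inside right stance, before left heel strike
  expect_true(all(truth$onsets[pert] >= ev$rhs[pert]))
  expect_true(all(truth$onsets[pert] < ev$lhs[pert]))
  # belt perturbed only around perturbed strides; catch strides clean
  v <- trial$treadmill$belt_right_mps
  for (s in which(truth$labels == "catch")) {
    win <- ev$rhs[s]:ev$rto[s]
    expect_true(all(abs(v[win] - 1.0) < 1e-12))
  }
  expect_equal(max(v), 1.4)
})

test_that("response deltas decay exponentially from the first perturbed stride", {
  resp <- response_model(delta = c(bos_ap_lhs = -0.05),
                         catch_delta = c(bos_ap_lhs = -0.02), tau = 6)
  trial <- generate_trial(gait_config(noise_sd = 0), perturbation_spec("none"),
                          resp, blocks = short_blocks(), seed = 9)
  ad <- trial$truth$applied_deltas
  first <- which(ad$label == "perturbed")[1]
  expect_equal(ad$bos_ap_lhs[first], -0.05)
  pert <- ad[ad$label == "perturbed", ]
  k <- pert$stride - first
  expect_equal(pert$bos_ap_lhs, -0.05 * exp(-k / 6), tolerance = 1e-12)
  catches <- ad[ad$label == "catch" & ad$stride > first, ]
  expect_equal(catches$bos_ap_lhs,
               -0.02 * exp(-(catches$stride - first) / 6), tolerance = 1e-12)
  expect_true(all(ad$bos_ap_lhs[ad$label %in% c("pre", "post")] == 0))
})
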