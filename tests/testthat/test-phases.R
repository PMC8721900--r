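test_that("phase labels follow the protocol definitions", {
  labels <- c(rep("pre", 60),
              c("perturbed", "perturbed", "catch", "perturbed", "perturbed"),
              rep(c("perturbed", "perturbed", "perturbed", "catch", "perturbed"), 3),
              rep("post", 8))
  ph <- assign_phases(labels)
  expect_equal(sum(ph$phase_lhs == "pre"), 49)  # first 11 excluded
  pert <- which(labels == "perturbed")
  # lhs: first three perturbed strides; lto: perturbed strides 2-4
  expect_equal(which(ph$phase_lhs == "early_perturbed"), pert[1:3])
  expect_equal(which(ph$phase_lto == "early_perturbed"), pert[2:4])
  expect_equal(which(ph$phase_lhs == "late_perturbed"), utils::tail(pert, 3))
  catches <- which(labels == "catch")
  expect_equal(which(ph$phase_lhs == "early_catch"), catches[1:2])
  expect_equal(which(ph$phase_lhs == "late_catch"), utils::tail(catches, 2))
  post <- which(labels == "post")
  expect_equal(which(ph$phase_lhs == "early_post"), post[1:3])
  expect_equal(which(ph$phase_lhs == "late_post"), utils::tail(post, 3))
})

test_that("phase sets are disjoint and never mix perturbed with catch strides", {
  for (seed in 1:15) {
    sched <- generate_schedule(25, seed = seed)
    labels <- c(rep("pre", 14), sched$labels, rep("post", 7))
    ph <- assign_phases(labels)
    for (col in c("phase_lhs", "phase_lto")) {
      expect_true(all(ph[[col]][ph$label == "catch"] %in%
                        c("early_catch", "late_catch", "unlabeled")))
      expect_true(all(ph[[col]][ph$label == "perturbed"] %in%
                        c("early_perturbed", "late_perturbed", "unlabeled")))
      tab <- table(ph[[col]])
      expect_lte(tab[["early_perturbed"]], 3)
      expect_lte(tab[["late_perturbed"]], 3)
    }
  }
})

test_that("phase assignment errors name the impossible phase", {
  expect_error(assign_phases(rep("pre", 11)), "pre")
  expect_error(assign_phases(c(rep("pre", 12), rep("perturbed", 4))),
               "late_perturbed|early and late")
  expect_error(assign_phases(c(rep("pre", 12), rep("catch", 3))),
               "catch")
  expect_error(assign_phases(c(rep("pre", 12), rep("post", 4))),
               "post")
})

test_that("outlier screening removes strictly beyond 3 SD, single pass", {
  expect_equal(remove_outliers(rep(2.2, 10))$n_removed, 0)
  base <- c(-1.6, -1.2, -0.4, -0.1, 0.2, 0.3, 0.8, 1.1, 1.4)
  # one of 10 values at mean + 3.5 SD of the others -> that one removed
  out <- remove_outliers(c(base, mean(base) + 3.5 * stats::sd(base)))
  expect_equal(out$n_removed, 1)
  expect_false(out$keep[10])
  expect_equal(out$values, base)
  # boundary: a value at exactly 3 SD is retained ("beyond" is strict)
  v3 <- mean(base) + 3 * stats::sd(base)
  expect_equal(remove_outliers(c(base, v3))$n_removed, 0)
  expect_equal(remove_outliers(c(base, v3 + 0.05))$n_removed, 1)
  # too few values: nothing removed
  expect_equal(remove_outliers(c(0, 100))$n_removed, 0)
})

test_that("aggregation averages within phases and is order invariant", {
  res <- fixture_result()
  pt <- aggregate_phases(res$stability, res$phases)
  perm <- res$stability[sample.int(nrow(res$stability)), ]
  pt2 <- aggregate_phases(perm, res$phases)
  key <- function(d) d[order(d$metric, d$event, d$phase), c("value", "n")]
  expect_equal(key(pt2), key(pt), ignore_attr = TRUE)
  # single-stride phase: mean equals the stride value
  one <- res$stability[res$stability$event == "lhs" & res$stability$stride == 20, ]
  ph1 <- res$phases
  ph1$phase_lhs <- ifelse(ph1$stride == 20, "early_post", "unlabeled")
  pt1 <- aggregate_phases(res$stability[res$stability$event == "lhs", ], ph1)
  expect_equal(pt1$value[pt1$metric == "mos_ap"], one$mos_ap)
  # identical phases give zero contrast, and |delta| = abs(delta)
  ctr <- phase_contrasts(pt)
  expect_equal(ctr$abs_delta, abs(ctr$delta))
  steady <- ctr[ctr$phase_a == "pre" & ctr$phase_b == "early_perturbed", ]
  expect_true(all(abs(steady$delta) < 1e-8))  # steady fixture: no change
})

test_that("a margin disruption sized at 41.3% of the pre margin is recovered within 2% at zero noise", {
  base <- fixture_result()$phase_table
  pre_mos <- base$value[base$metric == "mos_ap" & base$event == "lhs" &
                          base$phase == "pre"]
  inj <- -0.413 * pre_mos  # delivered through the foot-placement channel
  resp <- response_model(delta = c(bos_ap_lhs = inj), tau = Inf)
  trial <- generate_trial(gait_config(noise_sd = 0), perturbation_spec("none"),
                          resp, blocks = short_blocks(), seed = 17)
  res <- process_trial(trial)
  cval <- function(ctr, m) ctr$delta[ctr$metric == m & ctr$event == "lhs" &
                                       ctr$phase_b == "early_perturbed"]
  # the foot-placement (BOS) delta is recovered as injected
  expect_equal(cval(res$contrasts, "bos_ap"), inj, tolerance = 0.02 * abs(inj))
  # generator ground truth for the margin: metrics evaluated on the raw
  # noise-free markers at the ground-truth event frames (the moved ankle
  # shortens the pendulum, so the margin change is not exactly the BOS
  # delta); the full pipeline must recover that truth within 2%
  truth_stab <- compute_stability(trial$markers, trial$treadmill,
                                  trial$truth$events, trial$fs)
  truth_ctr <- phase_contrasts(aggregate_phases(truth_stab, res$phases))
  d_pipe <- cval(res$contrasts, "mos_ap")
  d_true <- cval(truth_ctr, "mos_ap")
  expect_equal(d_pipe, d_true, tolerance = 0.02 * abs(d_true))
  expect_lt(abs(d_true / pre_mos + 0.413), 0.05)  # close to the nominal size
})
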