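test_that("one-way rANOVA matches a hand-computed sum-of-squares decomposition", {
  m <- matrix(c(3.1, 4.0, 5.2,
                2.8, 4.4, 5.0,
                3.5, 4.1, 5.9), nrow = 3, byrow = TRUE,
              dimnames = list(NULL, c("a", "b", "c")))
  # independent decomposition, written out longhand
  grand <- mean(m)
  ss_phase <- 3 * sum((colMeans(m) - grand)^2)
  ss_subj <- 3 * sum((rowMeans(m) - grand)^2)
  ss_err <- sum((m - grand)^2) - ss_phase - ss_subj
  f_hand <- (ss_phase / 2) / (ss_err / 4)
  r <- rm_anova_oneway(m)
  expect_equal(r$F, f_hand, tolerance = 1e-12)
  expect_equal(r$df_num, 2); expect_equal(r$df_den, 4)
  expect_equal(r$partial_eta_sq, ss_phase / (ss_phase + ss_err),
               tolerance = 1e-12)
  expect_equal(r$p, stats::pf(f_hand, 2, 4, lower.tail = FALSE))
})

test_that("rANOVA is location invariant and NaN-safe on degenerate data", {
  set.seed(5)
  m <- matrix(rnorm(24), 6, 4)
  r0 <- rm_anova_oneway(m)
  r1 <- rm_anova_oneway(m + 100)
  expect_equal(r1$F, r0$F, tolerance = 1e-9)
  # affine rescaling leaves partial eta squared unchanged
  r2 <- rm_anova_oneway(3.7 * m - 2)
  expect_equal(r2$partial_eta_sq, r0$partial_eta_sq, tolerance = 1e-9)
  # identical cells
  rz <- rm_anova_oneway(matrix(4.2, 5, 3))
  expect_equal(rz$F, 0); expect_equal(rz$p, 1)
  expect_equal(rz$partial_eta_sq, 0)
  expect_error(rm_anova_oneway(matrix(1:3, 1, 3)), "2 subjects")
})

test_that("Tukey HSD uses the studentized range and dominates the pairwise t", {
  means <- c(pre = 5.0, early = 8.0, late = 6.5)
  th <- tukey_hsd(means, ms_error = 4, df_error = 18, n = 9,
                  pairs = list(c("pre", "early")))
  # q = |diff| / sqrt(MSe / n) by hand
  expect_equal(th$q, 3 / sqrt(4 / 9), tolerance = 1e-12)
  expect_equal(th$p_adjusted,
               stats::ptukey(4.5, nmeans = 3, df = 18, lower.tail = FALSE))
  # equal means: adjusted p = 1
  te <- tukey_hsd(c(a = 1, b = 1, c = 1), 2, 12, 8)
  expect_true(all(abs(te$p_adjusted - 1) < 1e-9))
  # multiplicity: adjusted p >= unadjusted paired-t p for the same contrast
  for (q in c(0.5, 1.5, 3, 4.5)) {
    p_tukey <- stats::ptukey(q, nmeans = 5, df = 20, lower.tail = FALSE)
    p_t <- 2 * stats::pt(-q / sqrt(2), df = 20)
    expect_gte(p_tukey, p_t)
  }
})

test_that("paired t and Cohen's d match hand computation and guard degeneracy", {
  x <- c(1.2, 0.8, 1.5, 1.1, 0.9)
  y <- c(1.0, 0.7, 1.1, 1.2, 0.6)
  r <- paired_t_d(x, y)
  d <- x - y
  expect_equal(r$t, mean(d) / (stats::sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_equal(r$cohen_d, mean(d) / stats::sd(d), tolerance = 1e-12)
  expect_equal(r$p, stats::t.test(x, y, paired = TRUE)$p.value)
  rav <- paired_t_d(x, y, d_variant = "dav")
  expect_equal(rav$cohen_d, mean(d) / ((stats::sd(x) + stats::sd(y)) / 2))
  # x == y: t = 0, d = 0; constant nonzero differences: error
  r0 <- paired_t_d(x, x)
  expect_equal(r0$t, 0); expect_equal(r0$cohen_d, 0); expect_equal(r0$p, 1)
  expect_error(paired_t_d(c(2, 3, 4), c(1, 2, 3)), "zero variance")
})

test_that("two-way rANOVA matches aov and gates follow-ups at alpha = 0.025", {
  set.seed(11)
  d <- expand.grid(subject = factor(1:10), A = factor(c("stick", "slip")),
                   B = factor(c("0.4", "0.2")))
  d$value <- rnorm(40, sd = 0.05) +
    0.30 * (d$A == "stick") * (d$B == "0.4")  # size effect only for stick
  r <- rm_anova_twoway(d, value = "value")
  a <- summary(stats::aov(value ~ A * B + Error(subject / (A * B)), data = d))
  expect_equal(r$effects$A$F,
               a[["Error: subject:A"]][[1]]["A", "F value"], tolerance = 1e-9)
  expect_equal(r$effects$B$F,
               a[["Error: subject:B"]][[1]]["B", "F value"], tolerance = 1e-9)
  expect_equal(r$effects$AB$F,
               a[["Error: subject:A:B"]][[1]]["A:B", "F value"],
               tolerance = 1e-9)
  # interaction present -> follow-ups run per condition at 0.025
  expect_false(is.null(r$followups))
  expect_equal(r$alpha_followup, 0.025)
  expect_true(r$followups$significant[r$followups$level_A == "stick"])
  expect_false(r$followups$significant[r$followups$level_A == "slip"])
  # purely additive noiseless effects: interaction SS is exactly zero
  d2 <- d
  d2$value <- 1 + 0.5 * (d2$A == "stick") + 0.2 * (d2$B == "0.4") +
    0.1 * as.numeric(d2$subject)
  r2 <- rm_anova_twoway(d2, value = "value")
  expect_equal(r2$effects$AB$F, 0)
})

test_that("assumption checks report Shapiro-Wilk, Levene and Mauchly", {
  set.seed(3)
  m <- matrix(rnorm(50), 10, 5)
  ch <- assumption_checks(m)
  expect_true(ch$shapiro$p > 0 && ch$shapiro$p <= 1)
  expect_true(ch$mauchly$p > 0 && ch$mauchly$p <= 1)
  # identical groups: Levene p = 1
  mm <- matrix(rnorm(8), 8, 3)
  expect_equal(assumption_checks(mm)$levene$p, 1, tolerance = 1e-9)
  # two levels: sphericity trivially satisfied
  expect_equal(assumption_checks(matrix(rnorm(16), 8, 2))$mauchly$p, 1)
})

test_that("Shapiro-Wilk p values are uniform under the null", {
  set.seed(1234)
  ps <- replicate(200, stats::shapiro.test(rnorm(100))$p.value)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
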