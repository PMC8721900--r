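#' One-way repeated-measures ANOVA
#'
#' Within-subject decomposition for a complete subjects x levels matrix:
#' F = MS_level / MS_(level x subject), with partial eta squared
#' SS_level / (SS_level + SS_error). Degenerate data (all cells equal) give
#' F = 0, p = 1, eta = 0.
#'
#' @param m numeric matrix, subjects in rows, within-subject levels (e.g.
#'   phases) in columns; no missing values.
#' @param effect name of the within-subject factor (reporting only).
#' @return Object of class `rm_anova`: list with effect, F, df_num, df_den,
#'   p, partial_eta_sq, plus the pieces needed for post hocs (cell means,
#'   ms_error, df_error, n).
#' @export
rm_anova_oneway <- function(m, effect = "phase") {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (anyNA(m)) stop("matrix must be complete (drop missing listwise first)",
                     call. = FALSE)
  s <- nrow(m); p <- ncol(m)
  if (s < 2 || p < 2)
    stop("need at least 2 subjects and 2 levels", call. = FALSE)
  grand <- mean(m)
  col_m <- colMeans(m); row_m <- rowMeans(m)
  ss_a <- s * sum((col_m - grand)^2)
  ss_s <- p * sum((row_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- max(0, ss_tot - ss_a - ss_s)
  df_a <- p - 1; df_err <- (p - 1) * (s - 1)
  ms_a <- ss_a / df_a; ms_err <- ss_err / df_err
  if (ms_err <= .Machine$double.eps * max(1, abs(grand))^2) {
    f <- if (ss_a <= .Machine$double.eps) 0 else Inf
  } else f <- ms_a / ms_err
  pval <- if (is.infinite(f)) 0 else if (f == 0 && ss_a == 0) 1 else
    stats::pf(f, df_a, df_err, lower.tail = FALSE)
  eta <- if (ss_a + ss_err > 0) ss_a / (ss_a + ss_err) else 0
  structure(list(effect = effect, F = f, df_num = df_a, df_den = df_err,
                 p = pval, partial_eta_sq = eta, means = col_m,
                 ms_error = ms_err, df_error = df_err, n = s,
                 ss = c(effect = ss_a, subject = ss_s, error = ss_err)),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("rANOVA [%s]: F(%d, %d) = %.4g, p = %.4g, partial eta^2 = %.4g\n",
              x$effect, x$df_num, x$df_den, x$F, x$p, x$partial_eta_sq))
  invisible(x)
}

#' Tukey HSD adjusted p values for a priori pairs
#'
#' Studentized-range test using the ANOVA error term: for levels i, j the
#' statistic is q = |mean_i - mean_j| / sqrt(MS_error / n), referred to the
#' studentized-range distribution with the full family size `n_means`
#' (conservative when only a subset of pairs is of a priori interest).
#'
#' @param means named vector of cell means.
#' @param ms_error ANOVA error mean square.
#' @param df_error error degrees of freedom.
#' @param n number of subjects per cell.
#' @param pairs list of length-2 character vectors naming the compared
#'   levels; default: all pairs.
#' @param n_means family size for the studentized range; defaults to
#'   `length(means)`.
#' @return data.frame with columns level_a, level_b, diff, q, p_adjusted.
#' @export
tukey_hsd <- function(means, ms_error, df_error, n, pairs = NULL,
                      n_means = length(means)) {
  if (is.null(names(means))) names(means) <- as.character(seq_along(means))
  if (is.null(pairs)) {
    cmb <- utils::combn(names(means), 2, simplify = FALSE)
    pairs <- cmb
  }
  se <- sqrt(ms_error / n)
  rows <- lapply(pairs, function(pr) {
    d <- means[[pr[2]]] - means[[pr[1]]]
    q <- if (se > 0) abs(d) / se else if (abs(d) > 0) Inf else 0
    p <- if (is.infinite(q)) 0 else
      stats::ptukey(q, nmeans = n_means, df = df_error, lower.tail = FALSE)
    data.frame(level_a = pr[1], level_b = pr[2], diff = d, q = q,
               p_adjusted = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired t test with Cohen's d
#'
#' Standard paired t test plus an effect size. The default Cohen's d is the
#' paired-difference standardisation d_z = mean(diff) / sd(diff); `"dav"`
#' standardises by the average of the two condition SDs instead.
#'
#' @param x,y paired numeric vectors.
#' @param d_variant `"dz"` (default) or `"dav"`.
#' @return list with t, df, p, cohen_d, mean_diff.
#' @export
paired_t_d <- function(x, y, d_variant = c("dz", "dav")) {
  d_variant <- match.arg(d_variant)
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  d <- x - y
  sd_d <- stats::sd(d)
  if (!is.finite(sd_d) || sd_d == 0) {
    if (all(d == d[1]) && d[1] == 0)
      return(list(t = 0, df = length(d) - 1, p = 1, cohen_d = 0, mean_diff = 0))
    stop("zero variance of paired differences: t is undefined", call. = FALSE)
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  cd <- switch(d_variant,
    dz = mean(d) / sd_d,
    dav = mean(d) / ((stats::sd(x) + stats::sd(y)) / 2)
  )
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, cohen_d = cd, mean_diff = mean(d))
}

#' Two-way repeated-measures ANOVA (both factors within subject)
#'
#' Full within-subject decomposition for a subjects x A x B design with one
#' observation per cell: each effect is tested against its own
#' effect-by-subject interaction (F_A = MS_A / MS_(A x S), etc.), with
#' partial eta squared SS_effect / (SS_effect + SS_error-term). When the
#' interaction is significant at `alpha`, follow-up paired t tests compare
#' the levels of `B` within each level of `A` at the Bonferroni-corrected
#' level `alpha_followup` (protocol: 0.025).
#'
#' @param data data.frame with columns `subject`, `A`, `B`, `value` (or
#'   remapped via the name arguments).
#' @param subject,A,B,value column names.
#' @param alpha significance level for the interaction gate.
#' @param alpha_followup Bonferroni-corrected level for follow-up tests.
#' @return list of class `rm_anova2`: per-effect tables (`A`, `B`, `AB`)
#'   with F, df, p, partial_eta_sq, and `followups` (possibly NULL).
#' @export
rm_anova_twoway <- function(data, subject = "subject", A = "A", B = "B",
                            value = "value", alpha = 0.05,
                            alpha_followup = 0.025) {
  d <- data.frame(s = factor(data[[subject]]), a = factor(data[[A]]),
                  b = factor(data[[B]]), y = data[[value]])
  if (anyNA(d$y)) stop("values must be complete", call. = FALSE)
  tab <- table(d$s, d$a, d$b)
  if (any(tab != 1))
    stop("design must be complete with one observation per subject x A x B cell",
         call. = FALSE)
  ns <- nlevels(d$s); na <- nlevels(d$a); nb <- nlevels(d$b)
  if (ns < 2 || na < 2 || nb < 2)
    stop("need at least 2 subjects and 2 levels per factor", call. = FALSE)
  g <- mean(d$y)
  mean_by <- function(...) tapply(d$y, list(...), mean)
  ya <- mean_by(d$a); yb <- mean_by(d$b); ys <- mean_by(d$s)
  yab <- mean_by(d$a, d$b); yas <- mean_by(d$a, d$s); ybs <- mean_by(d$b, d$s)
  ss_a <- ns * nb * sum((ya - g)^2)
  ss_b <- ns * na * sum((yb - g)^2)
  ss_s <- na * nb * sum((ys - g)^2)
  ss_ab <- ns * sum((sweep(sweep(yab, 1, ya), 2, yb) + g)^2)
  ss_as <- nb * sum((sweep(sweep(yas, 1, ya), 2, ys) + g)^2)
  ss_bs <- na * sum((sweep(sweep(ybs, 1, yb), 2, ys) + g)^2)
  ss_tot <- sum((d$y - g)^2)
  ss_abs <- max(0, ss_tot - ss_a - ss_b - ss_s - ss_ab - ss_as - ss_bs)
  eff <- function(name, ss_e, df_e, ss_err, df_err) {
    ms_e <- ss_e / df_e; ms_err <- ss_err / df_err
    f <- if (ms_err > 0) ms_e / ms_err else if (ss_e > 0) Inf else 0
    p <- if (is.infinite(f)) 0 else if (f == 0 && ss_e == 0) 1 else
      stats::pf(f, df_e, df_err, lower.tail = FALSE)
    list(effect = name, F = f, df_num = df_e, df_den = df_err, p = p,
         partial_eta_sq = if (ss_e + ss_err > 0) ss_e / (ss_e + ss_err) else 0)
  }
  res <- list(
    A = eff(A, ss_a, na - 1, ss_as, (na - 1) * (ns - 1)),
    B = eff(B, ss_b, nb - 1, ss_bs, (nb - 1) * (ns - 1)),
    AB = eff(paste0(A, ":", B), ss_ab, (na - 1) * (nb - 1),
             ss_abs, (na - 1) * (nb - 1) * (ns - 1))
  )
  followups <- NULL
  if (res$AB$p < alpha && nb == 2) {
    lv_b <- levels(d$b)
    followups <- do.call(rbind, lapply(levels(d$a), function(al) {
      sub <- d[d$a == al, ]
      x <- sub$y[sub$b == lv_b[1]][order(sub$s[sub$b == lv_b[1]])]
      y <- sub$y[sub$b == lv_b[2]][order(sub$s[sub$b == lv_b[2]])]
      tt <- paired_t_d(x, y)
      data.frame(level_A = al, contrast = paste(lv_b[1], "vs", lv_b[2]),
                 t = tt$t, df = tt$df, p = tt$p, cohen_d = tt$cohen_d,
                 significant = tt$p < alpha_followup)
    }))
  }
  structure(list(effects = res, followups = followups,
                 alpha_followup = alpha_followup), class = "rm_anova2")
}

#' @export
print.rm_anova2 <- function(x, ...) {
  for (e in x$effects)
    cat(sprintf("  %s: F(%d, %d) = %.4g, p = %.4g, partial eta^2 = %.4g\n",
                e$effect, e$df_num, e$df_den, e$F, e$p, e$partial_eta_sq))
  if (!is.null(x$followups)) {
    cat("  follow-up paired t (alpha =", x$alpha_followup, "):\n")
    print(x$followups)
  }
  invisible(x)
}

#' Distributional assumption checks
#'
#' Reported alongside the ANOVAs (not used as gates): Shapiro-Wilk W on the
#' within-subject residuals (cell value minus subject and level means plus
#' the grand mean), Levene's test (centred on the mean) for homogeneity of
#' variance across levels, and Mauchly's test of sphericity. With only two
#' levels sphericity holds trivially and W = 1, p = 1 is returned.
#'
#' @param m subjects x levels matrix.
#' @return list with `shapiro` (W, p), `levene` (F, p), `mauchly` (W, p).
#' @export
assumption_checks <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  s <- nrow(m); p <- ncol(m)
  grand <- mean(m)
  resid <- m - outer(rowMeans(m), rep(1, p)) -
    outer(rep(1, s), colMeans(m)) + grand
  sw <- if (stats::sd(resid) > 0) {
    swt <- stats::shapiro.test(as.vector(resid))
    list(W = unname(swt$statistic), p = swt$p.value)
  } else list(W = NA_real_, p = NA_real_)  # degenerate: zero residuals
  long <- data.frame(y = as.vector(m),
                     g = factor(rep(seq_len(p), each = s)))
  lev <- car::leveneTest(y ~ g, data = long, center = mean)
  if (p < 3) {
    mau <- list(W = 1, p = 1)
  } else {
    fit <- stats::lm(m ~ 1)
    mt <- stats::mauchly.test(fit, X = ~1)
    mau <- list(W = unname(mt$statistic), p = mt$p.value)
  }
  list(
    shapiro = sw,
    levene = list(F = lev[1, "F value"], p = lev[1, "Pr(>F)"]),
    mauchly = mau
  )
}
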