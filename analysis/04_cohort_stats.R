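#!/usr/bin/env Rscript
# Statistical layer over the cohort phase tables written by
# 03_cohort_phases.R, following the protocol's analysis plan:
#  - per condition & metric: one-way rANOVA over the perturbed-walking
#    phases with Tukey HSD on the a priori pairs and paired Cohen's d;
#  - per condition & metric: one-way rANOVA over the catch phases
#    (feedforward probe);
#  - |delta BOS| vs |delta XCOM| paired t within phase comparisons;
#  - two-way rANOVA (condition stick/slip x size 0.4/0.2) on |delta|
#    metrics with Bonferroni-corrected follow-ups (alpha = 0.025).
# Writes results/stats_oneway.csv, stats_pairwise.csv, stats_components.csv
# and stats_twoway.csv.

source("analysis/00_config.R")

pt <- read.csv("results/cohort_phase_tables.csv")
ctr <- read.csv("results/cohort_contrasts.csv")

pert_phases <- c("pre", "early_perturbed", "late_perturbed",
                 "early_post", "late_post")
pert_pairs <- list(c("pre", "early_perturbed"),
                   c("early_perturbed", "late_perturbed"),
                   c("early_post", "late_post"))
catch_phases <- c("pre", "early_catch", "late_catch")
catch_pairs <- list(c("pre", "early_catch"), c("pre", "late_catch"),
                    c("early_catch", "late_catch"))
metrics <- c("mos_ap", "mos_ml", "bos_ap", "bos_ml", "xcom_ap", "xcom_ml")

oneway <- list(); pairwise <- list()
for (cond in CONDITIONS) {
  sub <- pt[pt$condition == cond, ]
  for (ev in c("lhs", "lto")) for (metric in metrics) {
    for (design in c("perturbed", "catch")) {
      phs <- if (design == "perturbed") pert_phases else catch_phases
      prs <- if (design == "perturbed") pert_pairs else catch_pairs
      m <- phase_matrix(sub, metric, ev, phs)
      r <- cohort_oneway(m, pairs = prs)
      oneway[[length(oneway) + 1]] <- data.frame(
        condition = cond, design = design, metric = metric, event = ev,
        F = r$anova$F, df_num = r$anova$df_num, df_den = r$anova$df_den,
        p = r$anova$p, partial_eta_sq = r$anova$partial_eta_sq,
        n_subjects = r$anova$n,
        shapiro_p = r$assumptions$shapiro$p,
        levene_p = r$assumptions$levene$p,
        mauchly_p = r$assumptions$mauchly$p
      )
      if (!is.null(r$pairwise)) {
        pw <- r$pairwise
        pw$condition <- cond; pw$design <- design
        pw$metric <- metric; pw$event <- ev
        pairwise[[length(pairwise) + 1]] <- pw
      }
    }
  }
}
oneway <- do.call(rbind, oneway)
pairwise <- do.call(rbind, pairwise)
write.csv(oneway, "results/stats_oneway.csv", row.names = FALSE)
write.csv(pairwise, "results/stats_pairwise.csv", row.names = FALSE)

# |delta BOS| vs |delta XCOM| within phase comparisons (margin components)
comp <- list()
for (cond in CONDITIONS) for (ev in c("lhs", "lto")) for (ax in c("ap", "ml")) {
  for (pb in c("early_perturbed", "late_perturbed")) {
    pa <- if (pb == "early_perturbed") "pre" else "early_perturbed"
    sel <- function(metric) {
      s <- ctr[ctr$condition == cond & ctr$event == ev & ctr$metric == metric &
                 ctr$phase_a == pa & ctr$phase_b == pb, ]
      s$abs_delta[order(s$subject)]
    }
    b <- sel(paste0("bos_", ax)); x <- sel(paste0("xcom_", ax))
    if (!length(b) || stats::sd(b - x) == 0) next
    tt <- paired_t_d(b, x)
    comp[[length(comp) + 1]] <- data.frame(
      condition = cond, event = ev, axis = ax,
      comparison = paste(pa, "vs", pb),
      mean_abs_dBOS = mean(b), mean_abs_dXCOM = mean(x),
      t = tt$t, p = tt$p, cohen_d = tt$cohen_d
    )
  }
}
comp <- do.call(rbind, comp)
write.csv(comp, "results/stats_components.csv", row.names = FALSE)

# two-way rANOVA: condition (stick, slip) x size (0.4, 0.2) on |delta|
twoway <- list()
for (ev in c("lhs", "lto")) for (metric in c("mos_ap", "bos_ap", "xcom_ap")) {
  for (pb in c("early_perturbed", "late_perturbed")) {
    pa <- if (pb == "early_perturbed") "pre" else "early_perturbed"
    sub <- ctr[ctr$metric == metric & ctr$event == ev &
                 ctr$phase_a == pa & ctr$phase_b == pb &
                 ctr$condition %in% c("Stick0.4", "Stick0.2",
                                      "Slip0.4", "Slip0.2"), ]
    d <- data.frame(
      subject = sub$subject,
      A = ifelse(grepl("Stick", sub$condition), "stick", "slip"),
      B = ifelse(grepl("0.4", sub$condition, fixed = TRUE), "0.4", "0.2"),
      value = sub$abs_delta
    )
    r <- rm_anova_twoway(d)
    row <- data.frame(metric = metric, event = ev,
                      comparison = paste(pa, "vs", pb))
    for (e in r$effects) {
      nm <- gsub("[^A-Za-z]", "_", e$effect)
      row[[paste0("F_", nm)]] <- e$F
      row[[paste0("p_", nm)]] <- e$p
      row[[paste0("eta_", nm)]] <- e$partial_eta_sq
    }
    row$followups <- if (is.null(r$followups)) "" else
      paste(sprintf("%s: p=%.3g d=%.2f%s", r$followups$level_A, r$followups$p,
                    r$followups$cohen_d,
                    ifelse(r$followups$significant, " *", "")),
            collapse = "; ")
    twoway[[length(twoway) + 1]] <- row
  }
}
twoway <- do.call(rbind, twoway)
write.csv(twoway, "results/stats_twoway.csv", row.names = FALSE)

# headline numbers
cat("\nHeadline: relative disruption of MOS_ap/MOS_ml at left heel strike\n")
for (cond in CONDITIONS) {
  metric <- if (cond %in% c("M1", "L1")) "mos_ml" else "mos_ap"
  sub <- pt[pt$condition == cond & pt$metric == metric & pt$event == "lhs", ]
  pre <- mean(sub$value[sub$phase == "pre"])
  early <- mean(sub$value[sub$phase == "early_perturbed"])
  pw <- pairwise[pairwise$condition == cond & pairwise$metric == metric &
                   pairwise$event == "lhs" & pairwise$design == "perturbed" &
                   pairwise$level_b == "early_perturbed", ]
  cat(sprintf("  %-9s %s: %+6.1f%% (Tukey p = %.2g, d = %.2f)\n",
              cond, metric, 100 * (early - pre) / abs(pre),
              if (nrow(pw)) pw$p_adjusted else NA,
              if (nrow(pw)) pw$cohen_d else NA))
}
cat("\nTables written to results/: stats_oneway.csv, stats_pairwise.csv,",
    "stats_components.csv, stats_twoway.csv\n")
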