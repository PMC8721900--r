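#' Run the full single-trial pipeline
#'
#' Chains the processing stages on one recording: zero-phase low-pass
#' filtering of all markers, kinematic gait-event detection, alignment of
#' detected strides to the protocol stride numbering, perturbation-onset
#' re-detection, stride-by-stride stability metrics, phase labelling and
#' per-phase aggregation with contrasts.
#'
#' @param trial a `trial_recording` (or a list with the same fields built
#'   from [read_markers()]/[read_treadmill()]/[read_truth()] output).
#' @param cutoff,order low-pass filter settings ([lowpass_filter()]).
#' @param band,rel_height heel-strike detector settings
#'   ([detect_heel_strikes()]).
#' @param g gravitational constant, m/s^2.
#' @return list with `filtered` (markers), `events` (detected, with
#'   `truth_stride`), `onsets`, `stability` (stride numbering aligned to the
#'   protocol), `phases`, `phase_table`, `contrasts`.
#' @export
process_trial <- function(trial, cutoff = 12, order = 4, band = 0.03,
                          rel_height = 0.2, g = 9.81) {
  fs <- trial$fs
  cycle_time <- 1 / trial$gait$cadence
  big <- do.call(cbind, trial$markers)
  bigf <- lowpass_filter(big, fs = fs, cutoff = cutoff, order = order)
  filtered <- lapply(seq_along(trial$markers), function(i) {
    m <- bigf[, (3 * i - 2):(3 * i), drop = FALSE]
    colnames(m) <- c("x", "y", "z")
    m
  })
  names(filtered) <- names(trial$markers)
  events <- detect_gait_events(filtered, fs, cycle_time, band = band,
                               rel_height = rel_height)
  events <- match_strides(events, trial$truth$events, fs,
                          tol_s = 0.25 * cycle_time)
  onsets <- find_onsets(filtered, events)
  ev <- events[!is.na(events$truth_stride), , drop = FALSE]
  ev$stride <- ev$truth_stride
  stability <- compute_stability(filtered, trial$treadmill, ev, fs, g = g)
  phases <- assign_phases(trial$truth$labels)
  phase_table <- aggregate_phases(stability, phases)
  contrasts <- phase_contrasts(phase_table)
  list(filtered = filtered, events = events, onsets = onsets,
       stability = stability, phases = phases, phase_table = phase_table,
       contrasts = contrasts)
}

#' Simulate and process a cohort for one perturbation condition
#'
#' Generates one trial per subject (subject-specific seeds and, optionally,
#' subject-jittered response deltas) and runs [process_trial()] on each.
#'
#' @param n_subjects number of subjects.
#' @param condition perturbation condition name.
#' @param gait a [gait_config()] shared by the cohort.
#' @param response a [response_model()]; per-subject deltas are scaled by
#'   `1 + rnorm(1, 0, subject_sd)`.
#' @param blocks block durations in minutes, as in [generate_trial()].
#' @param seed cohort seed; subject s uses `seed + 997 * s`.
#' @param subject_sd relative between-subject SD of the response deltas.
#' @return list with `phase_tables`, `contrasts` (long data.frames with a
#'   `subject` column) and `trials_truth` (per-subject applied deltas).
#' @export
simulate_cohort <- function(n_subjects, condition, gait, response,
                            blocks = c(pre = 2, perturb = 4, post = 2),
                            seed = 1L, subject_sd = 0) {
  pt <- list(); ct <- list(); tt <- list()
  spec <- perturbation_spec(condition, baseline_speed = gait$walking_speed)
  for (s in seq_len(n_subjects)) {
    s_seed <- as.integer(seed + 997 * s)
    resp <- response
    if (subject_sd > 0) {
      scl <- with_seed(s_seed, function() 1 + stats::rnorm(1, 0, subject_sd))
      resp <- response_model(delta = response$delta * scl,
                             catch_delta = response$catch_delta * scl,
                             tau = response$tau)
    }
    trial <- generate_trial(gait, spec, resp, blocks = blocks, seed = s_seed)
    res <- process_trial(trial)
    res$phase_table$subject <- s
    res$contrasts$subject <- s
    pt[[s]] <- res$phase_table
    ct[[s]] <- res$contrasts
    ad <- trial$truth$applied_deltas
    ad$subject <- s
    tt[[s]] <- ad
  }
  list(phase_tables = do.call(rbind, pt), contrasts = do.call(rbind, ct),
       trials_truth = do.call(rbind, tt))
}

#' Subjects x phases matrix for one metric and event
#'
#' Builds the complete subject-by-phase matrix used by the repeated-measures
#' ANOVA, with optional group-level outlier screening: within each phase,
#' values beyond 3 SD of the group mean are marked and the affected
#' subjects dropped listwise.
#'
#' @param phase_tables long phase table with a `subject` column (from
#'   [simulate_cohort()]).
#' @param metric,event which stability metric and evaluation event.
#' @param phases character vector of phases (matrix columns).
#' @param screen_outliers apply [remove_outliers()] per phase before the
#'   listwise drop.
#' @return numeric matrix (subjects kept) x (phases), with dimnames.
#' @export
phase_matrix <- function(phase_tables, metric, event, phases,
                         screen_outliers = TRUE) {
  sub <- phase_tables[phase_tables$metric == metric &
                        phase_tables$event == event &
                        phase_tables$phase %in% phases, , drop = FALSE]
  subjects <- sort(unique(sub$subject))
  m <- matrix(NA_real_, length(subjects), length(phases),
              dimnames = list(subjects, phases))
  for (i in seq_len(nrow(sub)))
    m[as.character(sub$subject[i]), sub$phase[i]] <- sub$value[i]
  if (anyNA(m))
    stop("incomplete phase table: missing ",
         paste(phases[colSums(is.na(m)) > 0], collapse = ", "), call. = FALSE)
  if (screen_outliers) {
    keep <- rep(TRUE, nrow(m))
    for (j in seq_len(ncol(m)))
      keep <- keep & remove_outliers(m[, j])$keep
    m <- m[keep, , drop = FALSE]
  }
  m
}

#' One-way rANOVA with Tukey HSD post hocs and effect sizes on a cohort
#'
#' The statistical unit of the protocol's first two hypotheses: a one-way
#' repeated-measures ANOVA over phases, and — when the phase effect is
#' significant at `alpha` — Tukey HSD tests on the a priori phase pairs,
#' each with a paired Cohen's d. Assumption checks are reported, not used
#' as gates.
#'
#' @param m subjects x phases matrix (see [phase_matrix()]).
#' @param pairs list of length-2 phase-name pairs for the post hocs.
#' @param alpha significance level gating the post hocs.
#' @return list with `anova` (class `rm_anova`), `pairwise` (data.frame or
#'   NULL), `assumptions`.
#' @export
cohort_oneway <- function(m, pairs, alpha = 0.05) {
  an <- rm_anova_oneway(m)
  pw <- NULL
  if (an$p < alpha) {
    pw <- tukey_hsd(an$means, an$ms_error, an$df_error, an$n, pairs = pairs)
    pw$cohen_d <- vapply(seq_len(nrow(pw)), function(i) {
      x <- m[, pw$level_b[i]]; y <- m[, pw$level_a[i]]
      d <- x - y
      if (stats::sd(d) == 0) 0 else mean(d) / stats::sd(d)
    }, numeric(1))
  }
  list(anova = an, pairwise = pw, assumptions = assumption_checks(m))
}
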