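.phase_levels <- c("pre", "early_perturbed", "late_perturbed", "early_catch",
                   "late_catch", "early_post", "late_post", "unlabeled")

#' Assign protocol phases to strides
#'
#' Labels every stride with its analysis phase from the per-stride protocol
#' labels (`"pre"`, `"perturbed"`, `"catch"`, `"post"`):
#' pre = all pre-block strides except the first 11 (belt spin-up);
#' early perturbed = first 3 perturbed strides — for left-toe-off metrics,
#' perturbed strides 2-4, since left toe off precedes the first perturbation
#' onset; late perturbed = last 3 perturbed strides; early/late catch =
#' first/last 2 catch strides; early/late post = first/last 3 post-block
#' strides. All other strides are `"unlabeled"`. Because the early/late lhs
#' and lto definitions differ, two label columns are returned.
#'
#' @param labels character vector, one protocol label per stride.
#' @return data.frame with columns stride, label, phase_lhs, phase_lto.
#' @export
assign_phases <- function(labels) {
  n <- length(labels)
  ph_lhs <- rep("unlabeled", n)
  ph_lto <- rep("unlabeled", n)
  take <- function(idx, k, head = TRUE, phase) {
    if (length(idx) < k)
      stop("not enough strides to define phase '", phase, "' (need ", k,
           ", have ", length(idx), ")", call. = FALSE)
    if (head) idx[seq_len(k)] else idx[(length(idx) - k + 1):length(idx)]
  }
  pre_idx <- which(labels == "pre")
  if (length(pre_idx) > 0) {
    if (length(pre_idx) <= 11)
      stop("not enough strides to define phase 'pre' (first 11 are excluded)",
           call. = FALSE)
    pre_keep <- pre_idx[-seq_len(11)]
    ph_lhs[pre_keep] <- ph_lto[pre_keep] <- "pre"
  }
  pert_idx <- which(labels == "perturbed")
  if (length(pert_idx) > 0) {
    e_lhs <- take(pert_idx, 3, TRUE, "early_perturbed")
    e_lto <- take(pert_idx, 4, TRUE, "early_perturbed (lto)")[2:4]
    l_both <- take(pert_idx, 3, FALSE, "late_perturbed")
    if (length(intersect(union(e_lhs, e_lto), l_both)))
      stop("perturbation block too short: early and late perturbed overlap",
           call. = FALSE)
    ph_lhs[e_lhs] <- "early_perturbed"; ph_lto[e_lto] <- "early_perturbed"
    ph_lhs[l_both] <- ph_lto[l_both] <- "late_perturbed"
  }
  catch_idx <- which(labels == "catch")
  if (length(catch_idx) > 0) {
    e <- take(catch_idx, 2, TRUE, "early_catch")
    l <- take(catch_idx, 2, FALSE, "late_catch")
    if (length(intersect(e, l)))
      stop("perturbation block too short: early and late catch overlap",
           call. = FALSE)
    ph_lhs[e] <- ph_lto[e] <- "early_catch"
    ph_lhs[l] <- ph_lto[l] <- "late_catch"
  }
  post_idx <- which(labels == "post")
  if (length(post_idx) > 0) {
    e <- take(post_idx, 3, TRUE, "early_post")
    l <- take(post_idx, 3, FALSE, "late_post")
    if (length(intersect(e, l)))
      stop("post block too short: early and late post overlap", call. = FALSE)
    ph_lhs[e] <- ph_lto[e] <- "early_post"
    ph_lhs[l] <- ph_lto[l] <- "late_post"
  }
  data.frame(stride = seq_len(n), label = labels,
             phase_lhs = ph_lhs, phase_lto = ph_lto)
}

#' Remove outliers beyond 3 standard deviations
#'
#' Single-pass screen: a value is dropped when it lies strictly beyond
#' `threshold` standard deviations from the mean, with mean and SD taken
#' over the *remaining* values of the data set (a value never masks
#' itself; with the value included, |z| cannot even reach 3 in samples of
#' ten, so the rule could never fire at group level). A value at exactly
#' `threshold` SD is retained ("beyond" is strict). All values are tested
#' against the original data in one pass; constant data loses nothing.
#'
#' @param x numeric vector.
#' @param threshold z-score threshold.
#' @return list with `values` (retained), `keep` (logical mask) and
#'   `n_removed`.
#' @export
remove_outliers <- function(x, threshold = 3) {
  n <- length(x)
  keep <- rep(TRUE, n)
  if (n >= 3) {
    sx <- sum(x); sxx <- sum(x^2)
    m_loo <- (sx - x) / (n - 1)
    var_loo <- pmax(0, (sxx - x^2 - (n - 1) * m_loo^2) / (n - 2))
    s_loo <- sqrt(var_loo)
    dev <- abs(x - m_loo)
    keep <- ifelse(s_loo > 0, dev / s_loo <= threshold, dev == 0)
  }
  list(values = x[keep], keep = keep, n_removed = sum(!keep))
}

.metric_cols <- c("mos_ap", "mos_ml", "bos_ap", "bos_ml", "xcom_ap", "xcom_ml")

#' Aggregate stability rows into a per-phase table
#'
#' Joins stability rows to phase labels by ground-truth stride index and
#' averages each metric over the strides of each phase, separately per
#' evaluation event (lhs metrics use `phase_lhs`, lto metrics `phase_lto`).
#'
#' @param stability output of [compute_stability()]; its `stride` column
#'   must be on the same numbering as `phases$stride` (use
#'   [match_strides()] when the rows come from detected events).
#' @param phases output of [assign_phases()].
#' @return data.frame with columns metric, event, phase, value (mean), n.
#' @export
aggregate_phases <- function(stability, phases) {
  out <- list()
  for (ev in unique(stability$event)) {
    sub <- stability[stability$event == ev, , drop = FALSE]
    phcol <- if (ev == "lhs") "phase_lhs" else "phase_lto"
    lab <- phases[[phcol]][match(sub$stride, phases$stride)]
    ok <- !is.na(lab) & lab != "unlabeled"
    if (!any(ok)) next
    vals <- as.matrix(sub[ok, .metric_cols])
    grp <- lab[ok]
    cnt <- rowsum(rep(1, sum(ok)), grp)
    means <- rowsum(vals, grp) / as.vector(cnt)
    out[[length(out) + 1]] <- data.frame(
      metric = rep(.metric_cols, each = nrow(means)), event = ev,
      phase = rep(rownames(means), length(.metric_cols)),
      value = as.vector(means),
      n = rep(as.vector(cnt), length(.metric_cols))
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.contrast_pairs <- list(
  c("pre", "early_perturbed"),
  c("early_perturbed", "late_perturbed"),
  c("early_post", "late_post"),
  c("pre", "early_catch"),
  c("pre", "late_catch"),
  c("early_catch", "late_catch")
)

#' Phase contrasts (delta and absolute delta)
#'
#' For the protocol's a priori phase pairs, computes
#' delta = value(phase B) - value(phase A) and its magnitude, per metric and
#' event. Pairs with a missing phase are skipped.
#'
#' @param phase_table output of [aggregate_phases()].
#' @return data.frame with columns metric, event, phase_a, phase_b, delta,
#'   abs_delta.
#' @export
phase_contrasts <- function(phase_table) {
  out <- list()
  for (pair in .contrast_pairs) {
    a <- phase_table[phase_table$phase == pair[1], , drop = FALSE]
    b <- phase_table[phase_table$phase == pair[2], , drop = FALSE]
    if (!nrow(a) || !nrow(b)) next
    key <- function(d) paste(d$metric, d$event)
    m <- match(key(a), key(b))
    ok <- !is.na(m)
    if (!any(ok)) next
    d <- b$value[m[ok]] - a$value[ok]
    out[[length(out) + 1]] <- data.frame(
      metric = a$metric[ok], event = a$event[ok],
      phase_a = pair[1], phase_b = pair[2],
      delta = d, abs_delta = abs(d)
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
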