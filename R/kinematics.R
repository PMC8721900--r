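#' Zero-phase low-pass Butterworth filter
#'
#' 4th-order Butterworth applied forward and backward (zero phase, effective
#' 8th-order magnitude response), the standard pre-processing for marker
#' trajectories before event detection. The series is extended by odd
#' reflection at both ends before filtering to suppress edge transients.
#'
#' @param x numeric vector or matrix (filtered per column).
#' @param fs sampling rate, Hz; must exceed twice the cutoff.
#' @param cutoff low-pass cutoff frequency, Hz.
#' @param order filter order of a single pass.
#' @return Filtered series, same shape as `x`.
#' @export
lowpass_filter <- function(x, fs, cutoff = 12, order = 4) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (fs <= 2 * cutoff)
    stop("sampling rate must exceed twice the filter cutoff", call. = FALSE)
  npad <- min(n - 1L, as.integer(3 * ceiling(fs / cutoff)))
  if (npad < 3 * order)
    stop("series too short for filter warm-up", call. = FALSE)
  bf <- signal::butter(order, cutoff / (fs / 2))
  # odd (point-mirrored) reflection padding, as in common filtfilt practice
  pre <- 2 * matrix(x[1, ], npad, ncol(x), byrow = TRUE) -
    x[(npad + 1L):2L, , drop = FALSE]
  post <- 2 * matrix(x[n, ], npad, ncol(x), byrow = TRUE) -
    x[(n - 1L):(n - npad), , drop = FALSE]
  xp <- rbind(pre, x, post)
  flip <- function(m) m[nrow(m):1L, , drop = FALSE]
  y <- flip(.iir(bf$b, bf$a, flip(.iir(bf$b, bf$a, xp))))
  y <- y[(npad + 1L):(npad + n), , drop = FALSE]
  if (vec) as.numeric(y) else y
}

# single-pass IIR difference equation, columnwise on a plain matrix
# (compiled kernel). The edge value is subtracted first (exact for a
# unit-DC-gain low-pass), so the zero-state start-up transient scales with
# the local signal variation and decays inside the reflection padding.
.iir <- function(b, a, x) {
  x0 <- matrix(x[1, ], nrow(x), ncol(x), byrow = TRUE)
  .iir_mat(as.numeric(b), as.numeric(a), x - x0) + x0
}

# second time-derivative by central differences (ends zero)
.second_deriv <- function(x, fs) {
  n <- length(x)
  a <- numeric(n)
  a[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) * fs^2
  a
}

#' First time-derivative of a position series
#'
#' Central differences in the interior, one-sided at the boundaries.
#'
#' @param x numeric vector or matrix (per column), m.
#' @param fs sampling rate, Hz.
#' @return Velocity series, m/s, same shape as `x`.
#' @export
com_velocity <- function(x, fs) {
  if (is.matrix(x)) return(apply(x, 2, com_velocity, fs = fs))
  n <- length(x)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  v[1] <- (x[2] - x[1]) * fs
  v[n] <- (x[n] - x[n - 1]) * fs
  v
}

#' Estimate the centre of mass from the four pelvis markers
#'
#' Unweighted per-frame mean of the LASI, RASI, LPSI and RPSI positions.
#'
#' @param lasi,rasi,lpsi,rpsi n x 3 matrices (x, y, z), m.
#' @return n x 3 matrix of COM positions.
#' @export
estimate_com <- function(lasi, rasi, lpsi, rpsi) {
  for (m in list(lasi, rasi, lpsi, rpsi)) {
    if (is.null(m)) stop("missing pelvis marker", call. = FALSE)
    if (!is.matrix(m) || ncol(m) != 3)
      stop("pelvis markers must be n x 3 matrices", call. = FALSE)
  }
  (lasi + rasi + lpsi + rpsi) / 4
}

#' Detect heel strikes from a heel marker trajectory
#'
#' A heel strike is a frame where the heel's vertical position is near the
#' ground (within `band` of the trial's 5th-percentile heel height) and its
#' vertical acceleration attains a local maximum. Candidate peaks closer
#' than half the nominal cycle time are reduced to the largest, and peaks
#' below `rel_height` of the strongest accepted candidate are discarded.
#'
#' @param z filtered heel vertical position, m.
#' @param fs sampling rate, Hz.
#' @param cycle_time nominal stride period, s.
#' @param band near-ground band height above the 5th-percentile heel
#'   height, m.
#' @param rel_height minimum peak acceleration relative to the largest
#'   candidate.
#' @return Integer vector of heel-strike frames (sorted).
#' @export
detect_heel_strikes <- function(z, fs, cycle_time, band = 0.03,
                                rel_height = 0.2) {
  n <- length(z)
  if (n < 5) return(integer(0))
  a <- .second_deriv(z, fs)
  ground <- stats::quantile(z, 0.05, names = FALSE)
  core <- 2:(n - 1)
  is_max <- a[core] > a[core - 1] & a[core] >= a[core + 1]
  cand <- core[is_max & a[core] > 0 & z[core] <= ground + band]
  if (!length(cand)) return(integer(0))
  cand <- cand[a[cand] >= rel_height * max(a[cand])]
  # greedy: strongest first, enforce minimum separation
  cand <- cand[order(a[cand], decreasing = TRUE)]
  minsep <- round(0.5 * cycle_time * fs)
  kept <- integer(0)
  for (f in cand)
    if (!length(kept) || all(abs(kept - f) >= minsep)) kept <- c(kept, f)
  sort(kept)
}

#' Detect toe offs between consecutive heel strikes
#'
#' Within each interval between two consecutive heel strikes, the toe off of
#' the transitioning foot is the frame at which that foot's toe marker
#' attains its maximum vertical acceleration.
#'
#' @param z filtered toe vertical position of the transitioning foot, m.
#' @param fs sampling rate, Hz.
#' @param intervals 2-column matrix of (start, end) frames, one row per
#'   heel-strike interval.
#' @return Integer vector of toe-off frames, one per interval; empty if
#'   `intervals` has no rows (fewer than 2 heel strikes).
#' @export
detect_toe_offs <- function(z, fs, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) return(integer(0))
  a <- .second_deriv(z, fs)
  vapply(seq_len(nrow(intervals)), function(i) {
    s <- intervals[i, 1]; e <- intervals[i, 2]
    if (e - s < 2) return(NA_integer_)
    s + which.max(a[s:e]) - 1L
  }, integer(1))
}

#' Detect the full per-stride gait-event table
#'
#' Detects right and left heel strikes from the heel markers, then toe offs
#' in the corresponding heel-strike intervals, and assembles strides as
#' rhs < lto < lhs < rto. Incomplete boundary strides and strides with
#' missing or mis-ordered events are dropped.
#'
#' @param markers named list of filtered n x 3 marker matrices; requires
#'   `l_heel`, `r_heel`, `l_toe`, `r_toe`.
#' @param fs sampling rate, Hz.
#' @param cycle_time nominal stride period, s.
#' @param ... passed to [detect_heel_strikes()].
#' @return data.frame with columns stride, rhs, lto, lhs, rto (frames).
#' @export
detect_gait_events <- function(markers, fs, cycle_time, ...) {
  req <- c("l_heel", "r_heel", "l_toe", "r_toe")
  miss <- setdiff(req, names(markers))
  if (length(miss))
    stop("missing markers: ", paste(miss, collapse = ", "), call. = FALSE)
  rhs <- detect_heel_strikes(markers$r_heel[, 3], fs, cycle_time, ...)
  lhs <- detect_heel_strikes(markers$l_heel[, 3], fs, cycle_time, ...)
  if (length(rhs) < 2 || length(lhs) < 1)
    return(data.frame(stride = integer(0), rhs = integer(0),
                      lto = integer(0), lhs = integer(0), rto = integer(0)))
  rows <- list()
  for (i in seq_len(length(rhs) - 1)) {
    in_stride <- lhs[lhs > rhs[i] & lhs < rhs[i + 1]]
    if (length(in_stride) != 1) next  # gap or double: stride dropped
    rows[[length(rows) + 1]] <- c(rhs = rhs[i], lhs = in_stride,
                                  rhs_next = rhs[i + 1])
  }
  if (!length(rows))
    return(data.frame(stride = integer(0), rhs = integer(0),
                      lto = integer(0), lhs = integer(0), rto = integer(0)))
  m <- do.call(rbind, rows)
  lto <- detect_toe_offs(markers$l_toe[, 3], fs, m[, c("rhs", "lhs")])
  rto <- detect_toe_offs(markers$r_toe[, 3], fs, m[, c("lhs", "rhs_next")])
  out <- data.frame(stride = seq_len(nrow(m)), rhs = m[, "rhs"], lto = lto,
                    lhs = m[, "lhs"], rto = rto)
  ok <- !is.na(out$lto) & !is.na(out$rto) &
    out$rhs < out$lto & out$lto < out$lhs & out$lhs < out$rto
  out <- out[ok, , drop = FALSE]
  out$stride <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Match detected strides to ground-truth stride indices
#'
#' Assigns each detected stride the index of the ground-truth stride whose
#' right heel strike is nearest (within `tol_s`); unmatched strides get NA.
#'
#' @param events detected event table from [detect_gait_events()].
#' @param truth_events ground-truth event table (columns stride, rhs).
#' @param fs sampling rate, Hz.
#' @param tol_s matching tolerance, s.
#' @return `events` with an added `truth_stride` column.
#' @export
match_strides <- function(events, truth_events, fs, tol_s = 0.25) {
  if (nrow(events) == 0) {
    events$truth_stride <- integer(0)
    return(events)
  }
  idx <- vapply(events$rhs, function(f) {
    d <- abs(truth_events$rhs - f)
    j <- which.min(d)
    if (d[j] <= tol_s * fs) truth_events$stride[j] else NA_integer_
  }, integer(1))
  events$truth_stride <- idx
  events
}
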