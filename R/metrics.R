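#' Equivalent pendulum length
#'
#' Euclidean 3-D distance from the leading leg's lateral-malleolus (ankle)
#' marker to the COM at the event frame, used in the inverted-pendulum
#' eigenfrequency sqrt(g / l).
#'
#' @param ankle length-3 numeric (x, y, z), m.
#' @param com length-3 numeric (x, y, z), m.
#' @return Pendulum length l, m.
#' @export
pendulum_length <- function(ankle, com) {
  if (length(ankle) != 3 || length(com) != 3 || anyNA(ankle) || anyNA(com))
    stop("ankle and com must be finite length-3 vectors", call. = FALSE)
  l <- sqrt(sum((ankle - com)^2))
  if (l <= 1e-9)
    stop("degenerate pendulum: ankle and COM coincide", call. = FALSE)
  l
}

#' Extrapolated centre of mass (one axis)
#'
#' XCOM = COM + (V_COM - V_treadmill) / sqrt(g / l): the COM advanced by its
#' velocity relative to the moving support surface, scaled by the inverted
#' pendulum eigenfrequency. On the AP axis `v_treadmill` is the belt surface
#' velocity, on the ML axis the platform velocity.
#'
#' @param com COM position on the axis, m.
#' @param v_com COM velocity, m/s.
#' @param v_treadmill surface velocity on the same axis, m/s.
#' @param l pendulum length, m (> 0).
#' @param g gravitational constant, m/s^2.
#' @return XCOM coordinate, m. Vectorised over its first three arguments.
#' @export
extrapolate_com <- function(com, v_com, v_treadmill, l, g = 9.81) {
  if (any(l <= 0)) stop("pendulum length must be > 0", call. = FALSE)
  com + (v_com - v_treadmill) / sqrt(g / l)
}

#' Stride-by-stride stability metrics at left heel strike and left toe off
#'
#' Computes, for every stride at both evaluation events (`lhs`, reactive;
#' `lto`, anticipatory), the base of support (BOS), extrapolated centre of
#' mass (XCOM) and margin of stability (MOS = BOS - XCOM) in the
#' anterior-posterior and medial-lateral directions, plus the pendulum
#' length. Leading leg: left at `lhs`, right at `lto`.
#'
#' Geometry (all relative to the trailing foot): BOS_ap is the leading-toe
#' AP position minus the trailing-toe AP; XCOM_ap is the XCOM minus the
#' trailing toe. ML quantities use the ankle markers in a signed frame whose
#' positive direction points from the trailing toward the leading foot, so
#' BOS_ml > 0 in normal gait and crossover steps give BOS_ml < 0.
#'
#' The AP treadmill velocity is the instantaneous right-belt surface
#' velocity in the lab frame, i.e. minus the belt speed along the direction
#' of progression (a perturbation need not have finished by left heel
#' strike); the ML treadmill velocity is the platform velocity obtained by
#' differentiating the platform position.
#'
#' @param markers named list of (filtered) n x 3 marker matrices; requires
#'   the four pelvis markers plus `l_toe`, `r_toe`, `l_ankle`, `r_ankle`.
#' @param treadmill data.frame with `belt_right_mps` and `platform_y_m`.
#' @param events event table (columns stride, lto, lhs); rows with missing
#'   event frames are skipped.
#' @param fs sampling rate, Hz.
#' @param g gravitational constant, m/s^2.
#' @return data.frame, one row per stride x event, with columns stride,
#'   event, leading, mos_ap, mos_ml, bos_ap, bos_ml, xcom_ap, xcom_ml,
#'   pendulum_l.
#' @export
compute_stability <- function(markers, treadmill, events, fs, g = 9.81) {
  com <- estimate_com(markers$LASI, markers$RASI, markers$LPSI, markers$RPSI)
  vcom <- com_velocity(com[, 1:2], fs)
  v_platform <- com_velocity(treadmill$platform_y_m, fs)
  one_event <- function(ev) {
    f <- events[[ev]]
    ok <- !is.na(f) & f >= 1 & f <= nrow(com)
    f <- f[ok]
    if (ev == "lhs") {
      lead_toe <- markers$l_toe; trail_toe <- markers$r_toe
      lead_ank <- markers$l_ankle; trail_ank <- markers$r_ankle
      sgn <- -1; leading <- "left"
    } else {
      lead_toe <- markers$r_toe; trail_toe <- markers$l_toe
      lead_ank <- markers$r_ankle; trail_ank <- markers$l_ankle
      sgn <- 1; leading <- "right"
    }
    l <- sqrt((lead_ank[f, 1] - com[f, 1])^2 + (lead_ank[f, 2] - com[f, 2])^2 +
                (lead_ank[f, 3] - com[f, 3])^2)
    if (any(l <= 1e-9))
      stop("degenerate pendulum: ankle and COM coincide", call. = FALSE)
    vt_ap <- -treadmill$belt_right_mps[f]
    xcom_x <- extrapolate_com(com[f, 1], vcom[f, 1], vt_ap, l, g)
    xcom_y <- extrapolate_com(com[f, 2], vcom[f, 2], v_platform[f], l, g)
    bos_ap <- lead_toe[f, 1] - trail_toe[f, 1]
    xcom_ap <- xcom_x - trail_toe[f, 1]
    bos_ml <- sgn * (lead_ank[f, 2] - trail_ank[f, 2])
    xcom_ml <- sgn * (xcom_y - trail_ank[f, 2])
    data.frame(
      stride = events$stride[ok], event = ev, leading = leading,
      mos_ap = bos_ap - xcom_ap, mos_ml = bos_ml - xcom_ml,
      bos_ap = bos_ap, bos_ml = bos_ml,
      xcom_ap = xcom_ap, xcom_ml = xcom_ml, pendulum_l = l
    )
  }
  out <- rbind(one_event("lhs"), one_event("lto"))
  out <- out[order(out$stride, out$event), , drop = FALSE]
  rownames(out) <- NULL
  out
}
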