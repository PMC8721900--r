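# Kinematic walker template + perturbation insertion.
#
# Timing template (stride period T, right heel strike at stride start):
#   rhs at 0.0 T, lto at 0.1 T, lhs at 0.5 T, rto at 0.6 T
# i.e. 60% duty factor and 10% double-support phases. Feet follow the belt
# during stance and a smooth (quintic) swing to the next planned landing.
# Heel/toe vertical profiles are shaped so that the heel's maximum vertical
# acceleration near the ground occurs at touchdown and the toe's at lift-off,
# matching the kinematic event definitions used by the pipeline.

.smoothstep <- function(u) u * u * u * (10 + u * (-15 + 6 * u))

# quintic Hermite segment matching position/velocity/acceleration at both
# ends; u in [0, 1], D = segment duration (velocities per second)
.quintic <- function(u, D, z0, v0, a0, z1, v1, a1) {
  v0 <- v0 * D; v1 <- v1 * D; a0 <- a0 * D^2; a1 <- a1 * D^2
  u2 <- u * u; u3 <- u2 * u; u4 <- u3 * u; u5 <- u4 * u
  z0 * (1 - 10 * u3 + 15 * u4 - 6 * u5) +
    v0 * (u - 6 * u3 + 8 * u4 - 3 * u5) +
    a0 * (u2 / 2 - 1.5 * u3 + 1.5 * u4 - 0.5 * u5) +
    z1 * (10 * u3 - 15 * u4 + 6 * u5) +
    v1 * (-4 * u3 + 7 * u4 - 3 * u5) +
    a1 * (0.5 * u3 - u4 + 0.5 * u5)
}

# Impact/push-off impulse: the vertical acceleration is a cos^2 pulse of
# amplitude A and half-width w, symmetric about the event instant, so the
# (zero-phase-filtered) acceleration maximum falls exactly on the event
# frame. Closed-form position for the landing cushion (ends at rest on the
# ground) and the push-off (starts at rest on the ground), u in [-1, 1]:
.cushion_z <- function(u, A, w) {
  A * w^2 * (1 + (u + 1)^2 / 4 - (cos(pi * u) + 1) / (2 * pi^2) - (u + 1))
}
.pushoff_z <- function(u, A, w) {
  A * w^2 * ((u + 1)^2 / 4 - (cos(pi * u) + 1) / (2 * pi^2))
}

# internal vertical-profile parameters shared by the trial builder and the
# steady-template trigger evaluation
.profile_params <- function(gait, T) {
  list(
    w = 0.04,                        # impulse half-width, s
    A_heel = 25, A_toe = 18,         # impulse peak accelerations, m/s^2
    heel_off = gait$duty_factor - 0.15,  # heel-off cycle fraction
    heel_peak = 0.80,                # heel apex cycle fraction
    toe_peak = 0.78,                 # toe apex cycle fraction
    w_ph = 0.04 / T
  )
}

# heel height over one cycle (phase 0 = ground-truth heel strike):
# landing cushion, flat stance, slow squared-quintic rise (negligible
# near-ground acceleration at heel-off), quintic descent into the cushion
.heel_z <- function(ph, gait, T) {
  pp <- .profile_params(gait, T)
  h <- gait$heel_lift
  z <- numeric(length(ph))
  i <- ph < pp$w_ph
  z[i] <- .cushion_z(ph[i] / pp$w_ph, pp$A_heel, pp$w)
  i <- ph >= pp$heel_off & ph < pp$heel_peak
  z[i] <- h * .smoothstep((ph[i] - pp$heel_off) /
                            (pp$heel_peak - pp$heel_off))^2
  i <- ph >= pp$heel_peak & ph < 1 - pp$w_ph
  D <- (1 - pp$w_ph - pp$heel_peak) * T
  z[i] <- .quintic((ph[i] - pp$heel_peak) / (1 - pp$w_ph - pp$heel_peak), D,
                   h, 0, 0, pp$A_heel * pp$w^2, -pp$A_heel * pp$w, 0)
  i <- ph >= 1 - pp$w_ph
  z[i] <- .cushion_z((ph[i] - 1) / pp$w_ph, pp$A_heel, pp$w)
  z
}

# toe height over one cycle (phase 0 = heel strike of the same foot):
# flat stance, push-off impulse centred at toe off (duty fraction),
# quintic rise to the apex, quintic descent to a zero-acceleration landing
.toe_z <- function(ph, gait, T) {
  pp <- .profile_params(gait, T)
  toff <- gait$duty_factor
  h <- gait$toe_lift
  z <- numeric(length(ph))
  i <- ph >= toff - pp$w_ph & ph < toff + pp$w_ph
  z[i] <- .pushoff_z((ph[i] - toff) / pp$w_ph, pp$A_toe, pp$w)
  i <- ph >= toff + pp$w_ph & ph < pp$toe_peak
  D <- (pp$toe_peak - toff - pp$w_ph) * T
  z[i] <- .quintic((ph[i] - toff - pp$w_ph) / (pp$toe_peak - toff - pp$w_ph),
                   D, pp$A_toe * pp$w^2, pp$A_toe * pp$w, 0, h, 0, 0)
  i <- ph >= pp$toe_peak
  z[i] <- h * (1 - .smoothstep((ph[i] - pp$toe_peak) / (1 - pp$toe_peak)))
  z
}

# pelvis-centre trajectory of the steady template (no response offsets)
.pelvis_center <- function(t, T, gait) {
  cbind(
    x = gait$sway_ap * sin(4 * pi * (t / T - 0.05)),
    y = gait$sway_ml * sin(2 * pi * (t / T - 0.05)),
    z = gait$pelvis_height + gait$bounce * cos(4 * pi * (t / T - 0.3))
  )
}

# piecewise stance/swing path of one foot.
# tc, xc, yc: contact times and planned landing positions (covering beyond
# the frame range); Bfun: cumulative belt displacement; pfun: platform pos.
.foot_path <- function(t, tc, xc, yc, Bfun, pfun, T, gait) {
  duty <- gait$duty_factor
  i <- findInterval(t, tc)
  if (any(i < 1) || any(i >= length(tc)))
    stop("internal: foot contacts do not cover the frame range")
  ph <- (t - tc[i]) / T
  t_off <- tc + duty * T
  x_off <- xc - (Bfun(t_off) - Bfun(tc))
  y_off <- yc + pfun(t_off) - pfun(tc)
  stance <- ph < duty
  x <- y <- numeric(length(t))
  x[stance] <- xc[i[stance]] - (Bfun(t[stance]) - Bfun(tc[i[stance]]))
  y[stance] <- yc[i[stance]] + pfun(t[stance]) - pfun(tc[i[stance]])
  sw <- !stance
  u <- (ph[sw] - duty) / (1 - duty)
  S <- .smoothstep(u)
  isw <- i[sw]
  x[sw] <- x_off[isw] + (xc[isw + 1L] - x_off[isw]) * S
  y[sw] <- y_off[isw] + (yc[isw + 1L] - y_off[isw]) * S
  list(x = x, y = y,
       z_heel = .heel_z(ph, gait, T), z_toe = .toe_z(ph, gait, T))
}

# first time within right stance at which the mid-stance trigger fires on
# the steady (noise-free, unperturbed) template; NA if it never fires
.template_onset_offset <- function(gait) {
  T <- 1 / gait$cadence
  fs <- gait$marker_rate
  off <- gait$marker_offsets
  t <- seq(0, 0.5 * T, by = 1 / (4 * fs))
  delta <- gait$duty_factor * T * gait$walking_speed
  foot_x <- delta / 2 - gait$walking_speed * t
  rtoe_ap <- foot_x + off$toe[1]
  rheel_ap <- foot_x + off$heel[1]
  # right toe still in stance over the scan window, but may carry the early
  # part of its push-off impulse near toe off; use the true profile
  rtoe_z <- .toe_z(t / T, gait, T)
  # left heel: contact at -T/2
  lheel_z <- .heel_z((t + 0.5 * T) / T, gait, T)
  pel <- .pelvis_center(t, T, gait)
  com_off <- (off$LASI + off$RASI + off$LPSI + off$RPSI) / 4
  com_ap <- pel[, "x"] + com_off[1]
  fire <- trigger_fires(com_ap, rtoe_ap, rheel_ap, lheel_z, rtoe_z)
  if (!any(fire)) return(NA_real_)
  t[which(fire)[1]]
}

#' Generate a synthetic perturbed-walking trial
#'
#' Builds a complete trial: periodic marker kinematics of treadmill walking,
#' belt-speed and platform-position time series with the condition's
#' perturbation profile inserted at the ground-truth right mid-stance of
#' every perturbed stride, a random catch-stride schedule, and injectable
#' stride-response deltas with exponential adaptation. Marker, belt and
#' platform series share a single clock at `gait$marker_rate`. The output
#' records full ground truth (events, onsets, schedule, applied deltas), so
#' every downstream stage can be validated by parameter recovery.
#'
#' @param gait a [gait_config()].
#' @param spec a [perturbation_spec()].
#' @param response a [response_model()].
#' @param blocks named numeric vector `c(pre=, perturb=, post=)` of block
#'   durations in minutes (protocol: 2/4/2).
#' @param seed integer seed; defaults to `gait$seed`. Identical seeds give
#'   identical recordings.
#' @return A `trial_recording`: list with `markers` (named list of n x 3
#'   matrices: LASI, RASI, LPSI, RPSI, l_heel, r_heel, l_toe, r_toe, l_ankle,
#'   r_ankle), `time`, `fs`, `treadmill` (data.frame: frame, time_s,
#'   belt_left_mps, belt_right_mps, platform_y_m) and `truth` (events,
#'   labels, onsets, blocks, applied response deltas).
#' @export
generate_trial <- function(gait, spec = perturbation_spec("none"),
                           response = response_model(),
                           blocks = c(pre = 2, perturb = 4, post = 2),
                           seed = gait$seed) {
  stopifnot(inherits(gait, "gait_config"), inherits(spec, "perturbation_spec"),
            inherits(response, "response_model"))
  if (abs(spec$baseline_speed - gait$walking_speed) > 1e-9)
    stop("spec baseline_speed must match gait walking_speed", call. = FALSE)
  if (!all(c("pre", "perturb", "post") %in% names(blocks)))
    stop("blocks must name pre, perturb and post durations (minutes)",
         call. = FALSE)
  T <- 1 / gait$cadence
  fs <- gait$marker_rate
  v0 <- gait$walking_speed
  off <- gait$marker_offsets
  w <- gait$step_width
  duty <- gait$duty_factor

  n_pre <- max(0L, round(blocks[["pre"]] * 60 / T))
  n_pert <- max(0L, round(blocks[["perturb"]] * 60 / T))
  n_post <- max(0L, round(blocks[["post"]] * 60 / T))
  n_total <- n_pre + n_pert + n_post
  if (n_total < 1) stop("trial must contain at least one stride", call. = FALSE)

  set.seed(seed)
  sched <- generate_schedule(n_pert, seed = NULL)
  labels <- c(rep("pre", n_pre), sched$labels, rep("post", n_post))

  onset_offset <- .template_onset_offset(gait)
  if (spec$kind != "none" && n_pert > 0 && !is.finite(onset_offset))
    stop("mid-stance trigger never fires for this gait configuration",
         call. = FALSE)

  # ---- event times (template timing; responses alter placement, not timing)
  pad <- 0.5 * T  # lead-in so stride 1's heel strike has full swing context
  rhs_t <- pad + (seq_len(n_total) - 1) * T
  lto_t <- rhs_t + 0.1 * T
  lhs_t <- rhs_t + 0.5 * T
  rto_t <- rhs_t + duty * T

  # ---- per-stride effective response deltas
  first_pert <- if (any(labels == "perturbed")) which(labels == "perturbed")[1] else NA_integer_
  eff <- matrix(0, n_total, length(.response_delta_names),
                dimnames = list(NULL, .response_delta_names))
  decay <- rep(0, n_total)
  if (!is.na(first_pert)) {
    k <- seq_len(n_total) - first_pert
    active <- k >= 0
    decay[active] <- exp(-k[active] / response$tau)
    for (s in which(active)) {
      if (labels[s] == "perturbed") eff[s, ] <- response$delta * decay[s]
      else if (labels[s] == "catch") eff[s, ] <- response$catch_delta * decay[s]
    }
  }

  # ---- frames
  t_end <- pad + n_total * T + 0.5 * T
  n_frames <- floor(t_end * fs) + 1L
  t <- (seq_len(n_frames) - 1) / fs

  # ---- treadmill state
  belt_right <- rep(v0, n_frames)
  platform <- rep(0, n_frames)
  onset_t <- rep(NA_real_, n_total)
  if (is.finite(onset_offset))
    onset_t[labels == "perturbed"] <- rhs_t[labels == "perturbed"] + onset_offset
  if (spec$kind != "none") {
    for (s in which(labels == "perturbed")) {
      i0 <- max(1L, floor(onset_t[s] * fs) + 1L)
      i1 <- min(n_frames, ceiling((onset_t[s] + spec$duration) * fs) + 1L)
      if (i0 > n_frames) next
      if (spec$kind == "belt")
        belt_right[i0:i1] <- make_belt_profile(spec, t[i0:i1], onset_t[s])
      else
        platform[i0:i1] <- make_shift_profile(spec, t[i0:i1], onset_t[s])
    }
  }

  # cumulative right-belt displacement (trapezoidal), linear outside range
  Bv <- cumsum(c(0, (belt_right[-1] + belt_right[-n_frames]) / 2)) / fs
  Bend <- Bv[n_frames]
  Bfun <- function(tt) {
    out <- numeric(length(tt))
    lo <- tt < 0; hi <- tt > t_end; mid <- !lo & !hi
    out[lo] <- v0 * tt[lo]
    out[hi] <- Bend + v0 * (tt[hi] - t[n_frames])
    out[mid] <- stats::approx(t, Bv, xout = tt[mid])$y
    out
  }
  Bfun_left <- function(tt) v0 * tt
  pfun <- function(tt) {
    out <- rep(0, length(tt))
    mid <- tt >= 0 & tt <= t_end
    out[mid] <- stats::approx(t, platform, xout = tt[mid])$y
    out
  }

  # ---- planned foot contacts (indexed so contact s belongs to stride s)
  delta_st <- duty * T * v0  # stance excursion at baseline speed
  idx_r <- 0:(n_total + 2L)
  tc_r <- pad + (idx_r - 1) * T
  xc_r <- rep(delta_st / 2, length(idx_r))
  yc_r <- rep(w / 2, length(idx_r))
  idx_l <- 0:(n_total + 2L)
  tc_l <- pad + (idx_l - 0.5) * T
  xc_l <- rep(delta_st / 2, length(idx_l))
  yc_l <- rep(-w / 2, length(idx_l))
  in_range <- function(s) s >= 1 & s <= n_total
  for (s in seq_len(n_total)) {
    ii <- which(idx_r == s)
    xc_r[ii] <- xc_r[ii] + eff[s, "bos_ap_lto"]
    yc_r[ii] <- yc_r[ii] + eff[s, "bos_ml_lto"]
    jj <- which(idx_l == s)
    xc_l[jj] <- xc_l[jj] + eff[s, "bos_ap_lhs"]
    yc_l[jj] <- yc_l[jj] - eff[s, "bos_ml_lhs"]
  }

  fp_r <- .foot_path(t, tc_r, xc_r, yc_r, Bfun, pfun, T, gait)
  fp_l <- .foot_path(t, tc_l, xc_l, yc_l, Bfun_left, pfun, T, gait)

  # ---- pelvis centre + XCOM response bumps (cos^2, half-width T/4; at the
  # bump centre the offset equals the delta and its velocity is zero, so
  # exactly the stated delta appears in XCOM at the event)
  pel <- .pelvis_center(t, T, gait)
  add_bump <- function(center, amp_x, amp_y) {
    if (amp_x == 0 && amp_y == 0) return(invisible(NULL))
    half <- T / 4
    i0 <- max(1L, floor((center - half) * fs) + 1L)
    i1 <- min(n_frames, ceiling((center + half) * fs) + 1L)
    if (i0 > n_frames || i1 < 1) return(invisible(NULL))
    u <- (t[i0:i1] - center) / half
    b <- cos(0.5 * pi * pmax(-1, pmin(1, u)))^2
    pel[i0:i1, "x"] <<- pel[i0:i1, "x"] + amp_x * b
    pel[i0:i1, "y"] <<- pel[i0:i1, "y"] + amp_y * b
    invisible(NULL)
  }
  for (s in seq_len(n_total)) {
    if (eff[s, "xcom_ap_lhs"] != 0 || eff[s, "xcom_ml_lhs"] != 0)
      add_bump(lhs_t[s], eff[s, "xcom_ap_lhs"], -eff[s, "xcom_ml_lhs"])
    if (eff[s, "xcom_ap_lto"] != 0 || eff[s, "xcom_ml_lto"] != 0)
      add_bump(lto_t[s], eff[s, "xcom_ap_lto"], eff[s, "xcom_ml_lto"])
  }

  # ---- marker assembly
  mk <- function(x, y, z) cbind(x = x, y = y, z = z)
  markers <- list(
    LASI = mk(pel[, 1] + off$LASI[1], pel[, 2] + off$LASI[2], pel[, 3] + off$LASI[3]),
    RASI = mk(pel[, 1] + off$RASI[1], pel[, 2] + off$RASI[2], pel[, 3] + off$RASI[3]),
    LPSI = mk(pel[, 1] + off$LPSI[1], pel[, 2] + off$LPSI[2], pel[, 3] + off$LPSI[3]),
    RPSI = mk(pel[, 1] + off$RPSI[1], pel[, 2] + off$RPSI[2], pel[, 3] + off$RPSI[3]),
    l_heel = mk(fp_l$x + off$heel[1], fp_l$y, fp_l$z_heel),
    r_heel = mk(fp_r$x + off$heel[1], fp_r$y, fp_r$z_heel),
    l_toe = mk(fp_l$x + off$toe[1], fp_l$y, fp_l$z_toe),
    r_toe = mk(fp_r$x + off$toe[1], fp_r$y, fp_r$z_toe),
    l_ankle = mk(fp_l$x, fp_l$y - off$ankle[2], off$ankle[3] + 0.7 * fp_l$z_heel),
    r_ankle = mk(fp_r$x, fp_r$y + off$ankle[2], off$ankle[3] + 0.7 * fp_r$z_heel)
  )
  if (gait$noise_sd > 0)
    for (m in names(markers))
      markers[[m]] <- markers[[m]] +
        matrix(stats::rnorm(3 * n_frames, 0, gait$noise_sd), n_frames, 3)

  to_frame <- function(tt) as.integer(round(tt * fs)) + 1L
  events <- data.frame(
    stride = seq_len(n_total),
    rhs = to_frame(rhs_t), lto = to_frame(lto_t),
    lhs = to_frame(lhs_t), rto = to_frame(rto_t)
  )
  truth <- list(
    events = events,
    labels = labels,
    blocks = c(pre = n_pre, perturb = n_pert, post = n_post),
    onsets = ifelse(is.na(onset_t), NA_integer_, to_frame(onset_t)),
    onset_offset_s = onset_offset,
    applied_deltas = data.frame(stride = seq_len(n_total), label = labels,
                                decay = decay, eff, check.names = FALSE),
    schedule = sched,
    seed = seed
  )
  structure(list(
    markers = markers, time = t, fs = fs,
    treadmill = data.frame(
      frame = seq_len(n_frames), time_s = t,
      belt_left_mps = rep(v0, n_frames), belt_right_mps = belt_right,
      platform_y_m = platform
    ),
    truth = truth, gait = gait, spec = spec, response = response
  ), class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat("<trial_recording>", x$spec$condition, "|",
      length(x$time), "frames @", x$fs, "Hz |",
      nrow(x$truth$events), "strides (pre/perturb/post =",
      paste(x$truth$blocks, collapse = "/"), ")\n")
  invisible(x)
}
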