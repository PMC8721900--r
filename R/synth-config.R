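#' Marker offsets for the kinematic walker template
#'
#' Offsets (metres) of each tracked marker from its segment reference point,
#' in the package coordinate frame: x = anterior-posterior (positive
#' anterior), y = medial-lateral (positive toward the right leg's lateral
#' side), z = up. Pelvis markers are offsets from the pelvis centre; foot
#' markers are offsets from the foot reference point of the *right* foot
#' (the y component is mirrored for the left foot).
#'
#' @return Named list of length-3 numeric vectors.
#' @export
default_marker_offsets <- function() {
  list(
    LASI = c(0.10, -0.12, 0.00),
    RASI = c(0.10,  0.12, 0.00),
    LPSI = c(-0.12, -0.05, 0.03),
    RPSI = c(-0.12,  0.05, 0.03),
    heel = c(-0.05, 0.00, 0.00),
    toe  = c(0.15,  0.00, 0.00),
    # lateral malleolus: offset laterally and above the sole
    ankle = c(0.00, 0.04, 0.08)
  )
}

#' Gait configuration for the synthetic walker
#'
#' Describes steady treadmill walking at a fixed belt speed. The walker is a
#' kinematic template (sinusoidal pelvis, smooth swing-foot trajectories),
#' not a dynamic simulation, so ground-truth gait events are exact. Walking
#' speed, step length and cadence are linked by the treadmill constraint
#' `walking_speed = 2 * step_length * cadence`; give any two (cadence is
#' derived when `NULL`).
#'
#' @param walking_speed baseline belt speed in m/s (both belts tied).
#' @param step_length anterior-posterior distance between the two feet at
#'   heel strike, m.
#' @param cadence stride rate in strides/s; derived from speed and step
#'   length when `NULL`.
#' @param step_width medial-lateral distance between the foot reference
#'   points, m.
#' @param pelvis_height mean height of the pelvis centre, m.
#' @param noise_sd additive Gaussian noise on every marker coordinate, m.
#' @param marker_rate sampling rate of markers and treadmill state, Hz.
#' @param seed integer seed controlling all randomness of a trial.
#' @param duty_factor fraction of the stride cycle a foot is in stance.
#' @param heel_lift,toe_lift peak swing height of heel and toe markers, m.
#' @param sway_ml,sway_ap,bounce pelvis oscillation amplitudes (ML at stride
#'   frequency, AP and vertical at step frequency), m.
#' @param marker_offsets see [default_marker_offsets()].
#' @return A `gait_config` object (list).
#' @export
gait_config <- function(walking_speed = 1.0,
                        step_length = 0.55,
                        cadence = NULL,
                        step_width = 0.12,
                        pelvis_height = 0.95,
                        noise_sd = 0,
                        marker_rate = 240,
                        seed = 1L,
                        duty_factor = 0.60,
                        heel_lift = 0.15,
                        toe_lift = 0.06,
                        sway_ml = 0.025,
                        sway_ap = 0.010,
                        bounce = 0.020,
                        marker_offsets = default_marker_offsets()) {
  if (!(walking_speed > 0)) stop("walking_speed must be > 0", call. = FALSE)
  if (!(step_length > 0)) stop("step_length must be > 0", call. = FALSE)
  if (is.null(cadence)) cadence <- walking_speed / (2 * step_length)
  if (!(cadence > 0)) stop("cadence must be > 0", call. = FALSE)
  if (!(step_width > 0)) stop("step_width must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (abs(walking_speed - 2 * step_length * cadence) > 1e-9)
    stop("inconsistent gait geometry: walking_speed must equal 2 * step_length * cadence",
         call. = FALSE)
  if (duty_factor <= 0.5 || duty_factor >= 1)
    stop("duty_factor must lie in (0.5, 1)", call. = FALSE)
  req <- c("LASI", "RASI", "LPSI", "RPSI", "heel", "toe", "ankle")
  if (!all(req %in% names(marker_offsets)))
    stop("marker_offsets must name: ", paste(req, collapse = ", "), call. = FALSE)
  structure(list(
    walking_speed = walking_speed, step_length = step_length,
    cadence = cadence, step_width = step_width,
    pelvis_height = pelvis_height, noise_sd = noise_sd,
    marker_rate = marker_rate, seed = as.integer(seed),
    duty_factor = duty_factor, heel_lift = heel_lift, toe_lift = toe_lift,
    sway_ml = sway_ml, sway_ap = sway_ap, bounce = bounce,
    marker_offsets = marker_offsets
  ), class = "gait_config")
}

#' Perturbation conditions
#'
#' The six perturbation conditions plus `"none"`. Stick conditions briefly
#' decelerate the right belt (to 0.6 or 0.8 m/s), slip conditions accelerate
#' it (to 1.4 or 1.2 m/s), and M1/L1 shift the platform 1 cm medially or
#' laterally relative to the right leg.
#'
#' @export
perturbation_conditions <- function() {
  c("none", "Stick0.4", "Stick0.2", "Slip0.2", "Slip0.4", "M1", "L1")
}

.default_belt_target <- function(condition, baseline) {
  switch(condition,
    "Stick0.4" = baseline - 0.4,
    "Stick0.2" = baseline - 0.2,
    "Slip0.2"  = baseline + 0.2,
    "Slip0.4"  = baseline + 0.4,
    baseline
  )
}

#' Specification of one perturbation condition
#'
#' @param condition one of [perturbation_conditions()].
#' @param baseline_speed tied belt speed outside perturbations, m/s.
#' @param target_belt_speed peak/trough belt speed of a stick or slip
#'   perturbation, m/s; defaults to the protocol value for `condition`.
#' @param belt_accel belt ramp acceleration magnitude, m/s^2.
#' @param shift_displacement peak platform displacement of M1/L1, m.
#' @param shift_max_accel maximum platform acceleration, m/s^2.
#' @param duration onset-to-termination duration of the perturbation, s.
#' @return A `perturbation_spec` object.
#' @export
perturbation_spec <- function(condition = "none",
                              baseline_speed = 1.0,
                              target_belt_speed = NULL,
                              belt_accel = 12.5,
                              shift_displacement = 0.01,
                              shift_max_accel = 3.6,
                              duration = 0.400) {
  condition <- match.arg(condition, perturbation_conditions())
  if (is.null(target_belt_speed))
    target_belt_speed <- .default_belt_target(condition, baseline_speed)
  if (!(duration > 0)) stop("duration must be > 0", call. = FALSE)
  if (!(belt_accel > 0)) stop("belt_accel must be > 0", call. = FALSE)
  if (!(shift_max_accel > 0)) stop("shift_max_accel must be > 0", call. = FALSE)
  if (shift_displacement <= 0) stop("shift_displacement must be > 0", call. = FALSE)
  kind <- if (condition %in% c("Stick0.4", "Stick0.2", "Slip0.2", "Slip0.4")) {
    "belt"
  } else if (condition %in% c("M1", "L1")) "shift" else "none"
  if (kind == "belt" &&
      2 * abs(target_belt_speed - baseline_speed) / belt_accel > duration)
    stop("infeasible belt ramp: 2*|target - baseline|/belt_accel exceeds duration",
         call. = FALSE)
  if (kind == "shift" &&
      4 * sqrt(shift_displacement / shift_max_accel) > duration)
    stop("infeasible platform shift: out-and-back bang-bang travel exceeds duration",
         call. = FALSE)
  structure(list(
    condition = condition, kind = kind,
    baseline_speed = baseline_speed,
    target_belt_speed = target_belt_speed, belt_accel = belt_accel,
    shift_displacement = shift_displacement,
    shift_max_accel = shift_max_accel, duration = duration
  ), class = "perturbation_spec")
}

.response_delta_names <- c(
  "bos_ap_lhs", "bos_ml_lhs", "xcom_ap_lhs", "xcom_ml_lhs",
  "bos_ap_lto", "bos_ml_lto", "xcom_ap_lto", "xcom_ml_lto"
)

#' Injectable stride-response model
#'
#' Controls how the synthetic walker's foot placement and pelvis trajectory
#' respond to perturbations, so the downstream pipeline can be tested by
#' parameter recovery. Deltas are expressed directly in the stability-metric
#' frame: `bos_*` deltas move the landing position of the foot that leads at
#' the named event (left for `lhs`, right for `lto` — the latter act as
#' anticipatory adjustments since the right foot lands before perturbation
#' onset); `xcom_*` deltas displace the pelvis smoothly around the event so
#' that exactly the stated offset appears in XCOM at that event. A positive
#' ML delta widens the step.
#'
#' Adaptation: a delta applied on the stride with (0-based) index `k` since
#' the first perturbed stride is scaled by `exp(-k / tau)`.
#'
#' @param delta named numeric vector of deltas (m) applied on perturbed
#'   strides; names among
#'   `bos_ap_lhs, bos_ml_lhs, xcom_ap_lhs, xcom_ml_lhs, bos_ap_lto,
#'   bos_ml_lto, xcom_ap_lto, xcom_ml_lto`.
#' @param catch_delta deltas applied on catch strides (anticipation probes).
#' @param tau adaptation time constant in strides; `Inf` disables decay.
#' @return A `response_model` object; with all deltas zero the generator
#'   emits unperturbed steady gait.
#' @export
response_model <- function(delta = numeric(0), catch_delta = numeric(0),
                           tau = Inf) {
  full <- function(x) {
    out <- stats::setNames(numeric(length(.response_delta_names)),
                           .response_delta_names)
    if (length(x)) {
      bad <- setdiff(names(x), .response_delta_names)
      if (length(bad) || is.null(names(x)))
        stop("unknown response delta name(s): ",
             paste(if (is.null(names(x))) "<unnamed>" else bad, collapse = ", "),
             call. = FALSE)
      out[names(x)] <- x
    }
    out
  }
  delta <- full(delta); catch_delta <- full(catch_delta)
  if (!all(is.finite(c(delta, catch_delta))))
    stop("response deltas must be finite", call. = FALSE)
  if (!(tau > 0)) stop("tau must be > 0", call. = FALSE)
  structure(list(delta = delta, catch_delta = catch_delta, tau = tau),
            class = "response_model")
}
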