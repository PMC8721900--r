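#' Belt-speed profile of a stick or slip perturbation
#'
#' Trapezoidal profile: the right belt ramps at `belt_accel` from the
#' baseline to the target speed, holds, and ramps back so that the whole
#' perturbation completes in `duration` seconds. Outside the perturbation
#' window the belt runs at baseline speed.
#'
#' @param spec a [perturbation_spec()] with a stick/slip condition.
#' @param t_grid numeric vector of times, s.
#' @param onset perturbation onset time on `t_grid`'s clock, s.
#' @return Belt speed (m/s) at each time of `t_grid`.
#' @export
make_belt_profile <- function(spec, t_grid, onset = 0) {
  stopifnot(inherits(spec, "perturbation_spec"))
  if (spec$kind != "belt")
    stop("make_belt_profile requires a stick/slip condition, got ",
         spec$condition, call. = FALSE)
  dv <- spec$target_belt_speed - spec$baseline_speed
  a <- spec$belt_accel
  rel <- t_grid - onset
  # deviation from baseline: ramp up, clamp at |dv|, ramp down to 0 at duration
  dev <- pmin(a * rel, a * (spec$duration - rel), abs(dv))
  dev <- pmax(dev, 0)
  dev[rel < 0 | rel > spec$duration] <- 0
  spec$baseline_speed + sign(dv) * dev
}

# position of a rest-to-rest bang-bang move of distance d (>0), accel a,
# evaluated at s in [0, t1] where t1 = 2*sqrt(d/a)
.bang_bang_pos <- function(s, d, a) {
  t1 <- 2 * sqrt(d / a)
  half <- t1 / 2
  ifelse(s <= half, 0.5 * a * s^2, d - 0.5 * a * (t1 - s)^2)
}

#' Platform-position profile of a medial or lateral shift perturbation
#'
#' Acceleration-limited out-and-back profile: bang-bang move (accelerate
#' then decelerate at `shift_max_accel`, with a mid-course acceleration
#' reversal) to the signed peak displacement, a dwell at the peak, and a
#' bang-bang return, completing exactly at `duration`. L1 (lateral, toward
#' the right leg's lateral side) is positive y; M1 (medial) is negative.
#'
#' @inheritParams make_belt_profile
#' @param spec a [perturbation_spec()] with condition `"M1"` or `"L1"`.
#' @return Platform ML position (m) at each time of `t_grid`.
#' @export
make_shift_profile <- function(spec, t_grid, onset = 0) {
  stopifnot(inherits(spec, "perturbation_spec"))
  if (spec$kind != "shift")
    stop("make_shift_profile requires condition M1 or L1, got ",
         spec$condition, call. = FALSE)
  d <- spec$shift_displacement
  a <- spec$shift_max_accel
  t1 <- 2 * sqrt(d / a)              # minimum one-way travel time
  dwell <- spec$duration - 2 * t1    # feasibility guaranteed by the spec object
  sgn <- if (spec$condition == "L1") 1 else -1
  rel <- t_grid - onset
  pos <- numeric(length(rel))
  out <- rel >= 0 & rel < t1
  hold <- rel >= t1 & rel < t1 + dwell
  back <- rel >= t1 + dwell & rel <= spec$duration
  pos[out] <- .bang_bang_pos(rel[out], d, a)
  pos[hold] <- d
  pos[back] <- d - .bang_bang_pos(rel[back] - t1 - dwell, d, a)
  sgn * pos
}

#' Random catch-stride schedule for the perturbation block
#'
#' Partitions the perturbation-block strides into consecutive batches of
#' `batch` strides and draws, uniformly at random, exactly one catch
#' (no-perturbation) stride per complete batch; the remaining strides are
#' perturbed. A final incomplete batch (fewer than `batch` strides) is all
#' perturbed with no catch, so the one-in-`batch` rule holds exactly for
#' every complete batch.
#'
#' @param n_strides number of strides in the perturbation block.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param batch batch size (protocol value 5).
#' @return A `perturbation_schedule` object: `labels` (character,
#'   `"perturbed"`/`"catch"` per stride) plus bookkeeping fields.
#' @export
generate_schedule <- function(n_strides, seed = NULL, batch = 5L) {
  stopifnot(n_strides >= 0, batch >= 1)
  draw <- function() {
    labels <- rep("perturbed", n_strides)
    n_batches <- n_strides %/% batch
    if (n_batches > 0) {
      pos <- sample.int(batch, n_batches, replace = TRUE)
      labels[(seq_len(n_batches) - 1L) * batch + pos] <- "catch"
    }
    labels
  }
  labels <- if (is.null(seed)) draw() else with_seed(seed, draw)
  structure(list(labels = labels, batch = as.integer(batch),
                 n_strides = as.integer(n_strides), seed = seed),
            class = "perturbation_schedule")
}

#' Evaluate a function under a temporary RNG seed
#'
#' Runs `expr_fun()` with the RNG seeded to `seed`, restoring the caller's
#' RNG state afterwards.
#'
#' @param seed integer seed.
#' @param expr_fun zero-argument function.
#' @keywords internal
with_seed <- function(seed, expr_fun) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr_fun()
}
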