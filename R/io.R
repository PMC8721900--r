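#' Write a trial recording to tidy CSV + JSON ground truth
#'
#' Writes `markers.csv` (frame, time_s, marker, x_m, y_m, z_m, long format),
#' `treadmill.csv` (frame, time_s, belt_left_mps, belt_right_mps,
#' platform_y_m) and `truth.json` (events, labels, schedule, onsets, applied
#' response deltas). Units are metres, seconds, Hz throughout.
#'
#' @param trial a `trial_recording`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "trial_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(trial$time)
  mk <- data.table::rbindlist(lapply(names(trial$markers), function(m) {
    data.table::data.table(
      frame = seq_len(n), time_s = trial$time, marker = m,
      x_m = trial$markers[[m]][, 1], y_m = trial$markers[[m]][, 2],
      z_m = trial$markers[[m]][, 3]
    )
  }))
  paths <- c(markers = file.path(dir, "markers.csv"),
             treadmill = file.path(dir, "treadmill.csv"),
             truth = file.path(dir, "truth.json"))
  data.table::fwrite(mk, paths["markers"])
  data.table::fwrite(trial$treadmill, paths["treadmill"])
  truth <- trial$truth
  truth$schedule <- list(labels = truth$schedule$labels,
                         batch = truth$schedule$batch)
  truth$fs <- trial$fs
  truth$condition <- trial$spec$condition
  truth$cadence <- trial$gait$cadence
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, na = "null", dataframe = "columns")
  invisible(paths)
}

#' Read a markers.csv file back into a marker set
#'
#' @param path path to a `markers.csv` written by [write_trial()].
#' @return list with `markers` (named list of n x 3 matrices), `time`, `fs`.
#' @export
read_markers <- function(path) {
  d <- data.table::fread(path)
  req <- c("frame", "time_s", "marker", "x_m", "y_m", "z_m")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("markers.csv missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- as.data.frame(d)
  markers <- lapply(split(d, factor(d$marker, levels = unique(d$marker))),
                    function(s) {
    s <- s[order(s$frame), ]
    cbind(x = s$x_m, y = s$y_m, z = s$z_m)
  })
  time <- sort(unique(d$time_s))
  fs <- 1 / stats::median(diff(time))
  list(markers = markers, time = time, fs = fs)
}

#' Read a treadmill.csv file
#'
#' @param path path to a `treadmill.csv` written by [write_trial()].
#' @return data.frame with frame, time_s, belt_left_mps, belt_right_mps,
#'   platform_y_m.
#' @export
read_treadmill <- function(path) {
  d <- as.data.frame(data.table::fread(path))
  req <- c("frame", "time_s", "belt_left_mps", "belt_right_mps",
           "platform_y_m")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("treadmill.csv missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  d
}

#' Read ground truth written by [write_trial()]
#'
#' @param path path to `truth.json`.
#' @return list with events (data.frame), labels, blocks, onsets, schedule,
#'   applied_deltas.
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$events <- as.data.frame(tr$events)
  tr$applied_deltas <- as.data.frame(tr$applied_deltas)
  tr
}

#' Reassemble a trial recording from files written by [write_trial()]
#'
#' Reconstructs the minimal `trial_recording` needed by [process_trial()]
#' (markers, treadmill state, ground truth and the cadence recorded in the
#' truth file).
#'
#' @param dir directory containing `markers.csv`, `treadmill.csv`,
#'   `truth.json`.
#' @return A `trial_recording`-like list.
#' @export
read_trial <- function(dir) {
  ms <- read_markers(file.path(dir, "markers.csv"))
  td <- read_treadmill(file.path(dir, "treadmill.csv"))
  truth <- read_truth(file.path(dir, "truth.json"))
  structure(list(
    markers = ms$markers, time = ms$time, fs = truth$fs,
    treadmill = td, truth = truth,
    gait = list(cadence = truth$cadence),
    spec = list(condition = truth$condition)
  ), class = "trial_recording")
}

#' Read a run configuration from YAML
#'
#' Sections mirror the generator and pipeline arguments: `gait:`,
#' `perturbation:`, `response:`, `blocks:`, `pipeline:`, `cohort:`.
#' Missing sections fall back to package defaults.
#'
#' @param path YAML file.
#' @return Named list of configuration sections.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (s in c("gait", "perturbation", "response", "blocks", "pipeline",
              "cohort"))
    if (is.null(cfg[[s]])) cfg[[s]] <- list()
  cfg
}
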