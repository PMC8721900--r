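#' Mid-stance perturbation trigger
#'
#' The perturbation-onset condition of the protocol: the trigger fires when
#' the vertical projection of the COM lies between the right heel and right
#' toe markers in the anterior-posterior direction (inclusive) and the left
#' heel marker is at least `height_threshold` (5 cm) higher than the right
#' toe marker. Vectorised over frames.
#'
#' @param com_ap COM anterior-posterior position, m.
#' @param r_toe_ap,r_heel_ap right toe / heel AP positions, m.
#' @param l_heel_z,r_toe_z left heel / right toe heights, m.
#' @param height_threshold minimum left-heel elevation above the right toe,
#'   m.
#' @return Logical vector: `TRUE` where the trigger fires.
#' @export
trigger_fires <- function(com_ap, r_toe_ap, r_heel_ap, l_heel_z, r_toe_z,
                          height_threshold = 0.05) {
  lo <- pmin(r_heel_ap, r_toe_ap)
  hi <- pmax(r_heel_ap, r_toe_ap)
  com_ap >= lo & com_ap <= hi & (l_heel_z - r_toe_z) >= height_threshold
}

#' Find per-stride perturbation onsets
#'
#' For each stride, the onset is the first frame in the right-stance
#' interval `[rhs, lhs)` at which [trigger_fires()] is true; `NA` when the
#' trigger never fires in that stride.
#'
#' @param markers named list of (filtered) n x 3 marker matrices; requires
#'   the four pelvis markers, `r_toe`, `r_heel` and `l_heel`.
#' @param events event table with columns `stride`, `rhs`, `lhs`.
#' @param height_threshold passed to [trigger_fires()].
#' @return data.frame with columns `stride` and `onset` (frame or NA).
#' @export
find_onsets <- function(markers, events, height_threshold = 0.05) {
  com <- estimate_com(markers$LASI, markers$RASI, markers$LPSI, markers$RPSI)
  fire <- trigger_fires(com[, 1], markers$r_toe[, 1], markers$r_heel[, 1],
                        markers$l_heel[, 3], markers$r_toe[, 3],
                        height_threshold)
  onset <- vapply(seq_len(nrow(events)), function(i) {
    idx <- events$rhs[i]:(events$lhs[i] - 1L)
    hit <- idx[fire[idx]]
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  data.frame(stride = events$stride, onset = onset)
}
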