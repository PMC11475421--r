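# Data association: IoU cost plus a trajectory direction-consistency term
# (observation-centric momentum), solved by the Hungarian algorithm, and the
# second-stage recovery association for lost tracks (OCR).

.BIG_COST <- 1e9  # sentinel for gated (infeasible) cells

#' Direction-consistency cost between a track and a candidate detection
#'
#' Penalises candidate links whose direction disagrees with the track's
#' recent motion. The track direction is taken between two real observations
#' `delta_t` frames apart (the reference observation is the latest one at or
#' before `last_frame - delta_t`, falling back to the oldest available); the
#' link direction runs from that same reference observation to the detection
#' centre. The cost is the absolute angle between the two directions,
#' normalised to `[0, 1]` by pi. A track with a single observation (or a
#' degenerate zero-length direction) has no defined momentum and costs 0.
#'
#' @param history data.frame of the track's real observations with columns
#'   `frame`, `u`, `v` (virtual observations are never part of history).
#' @param det_center numeric `(u, v)` centre of the candidate detection.
#' @param delta_t momentum horizon in frames.
#' @return cost in `[0, 1]`.
#' @export
velocity_consistency_cost <- function(history, det_center, delta_t = 3L) {
  n <- nrow(history)
  if (n < 2L) return(0)
  history <- history[order(history$frame), , drop = FALSE]
  last <- history[n, ]
  target <- last$frame - delta_t
  ref_idx <- which(history$frame <= target)
  ref <- if (length(ref_idx)) history[max(ref_idx), ] else history[1, ]
  d_track <- c(last$u - ref$u, last$v - ref$v)
  d_link <- c(det_center[1] - ref$u, det_center[2] - ref$v)
  if (all(d_track == 0) || all(d_link == 0)) return(0)
  ang <- atan2(d_track[2], d_track[1]) - atan2(d_link[2], d_link[1])
  abs(((ang + pi) %% (2 * pi)) - pi) / pi
}

#' Build the association cost matrix
#'
#' Cell `(i, j)` is `-IoU(predicted box of track i, detection box j) +
#' lambda * C_v(i, j)` where `C_v` is [velocity_consistency_cost()]. Cells
#' whose IoU falls below `iou_gate` are masked infeasible and can never be
#' matched.
#'
#' @param track_boxes matrix of predicted track boxes, one
#'   `(left, top, width, height)` row per track.
#' @param track_histories list of observation-history data.frames, parallel
#'   to `track_boxes` (see [velocity_consistency_cost()]).
#' @param det_boxes matrix of detection boxes, one row per detection.
#' @param lambda_weight weight of the direction-consistency term.
#' @param delta_t momentum horizon in frames.
#' @param iou_gate minimum IoU for a feasible pairing.
#' @return list with `values` (N x M numeric) and `feasible` (N x M logical).
#' @export
build_cost <- function(track_boxes, track_histories, det_boxes,
                       lambda_weight = 0.2, delta_t = 3L, iou_gate = 0.3) {
  n <- nrow(track_boxes); m <- nrow(det_boxes)
  ious <- iou_matrix(track_boxes, det_boxes)
  values <- -ious
  if (lambda_weight != 0 && n > 0L && m > 0L) {
    for (i in seq_len(n)) {
      hist_i <- track_histories[[i]]
      for (j in seq_len(m)) {
        center <- c(det_boxes[j, 1] + det_boxes[j, 3] / 2,
                    det_boxes[j, 2] + det_boxes[j, 4] / 2)
        values[i, j] <- values[i, j] +
          lambda_weight * velocity_consistency_cost(hist_i, center, delta_t)
      }
    }
  }
  list(values = values, feasible = ious >= iou_gate)
}

#' Solve a gated assignment problem
#'
#' Minimum-total-cost one-to-one matching over the feasible cells of a cost
#' matrix built by [build_cost()] (or any list with `values` and `feasible`).
#' Infeasible cells are never matched; unmatched rows and columns are
#' reported separately.
#'
#' @param cost list with `values` (N x M) and `feasible` (N x M logical).
#' @return list with `matches` (two-column integer matrix: track index,
#'   detection index), `unmatched_tracks` and `unmatched_detections`
#'   (integer vectors). The three parts partition all indices.
#' @export
solve_assignment <- function(cost) {
  values <- cost$values
  feasible <- cost$feasible
  n <- nrow(values); m <- ncol(values)
  empty <- list(matches = matrix(integer(0), 0, 2,
                                 dimnames = list(NULL, c("track", "detection"))),
                unmatched_tracks = seq_len(n),
                unmatched_detections = seq_len(m))
  if (n == 0L || m == 0L || !any(feasible)) return(empty)
  work <- values
  work[!feasible] <- .BIG_COST
  assign <- solve_lap(work)
  matches <- matrix(integer(0), 0, 2)
  for (i in seq_len(n)) {
    j <- assign[i]
    if (!is.na(j) && feasible[i, j]) matches <- rbind(matches, c(i, j))
  }
  if (nrow(matches)) matches <- matches[order(matches[, 1]), , drop = FALSE]
  colnames(matches) <- c("track", "detection")
  list(matches = matches,
       unmatched_tracks = setdiff(seq_len(n), matches[, 1]),
       unmatched_detections = setdiff(seq_len(m), matches[, 2]))
}

#' Second-stage recovery association for lost tracks (OCR)
#'
#' After the primary association, lost tracks get a second chance: their
#' last *observed* box (not the Kalman prediction, which may have drifted
#' across the occlusion) is matched against the still-unmatched detections
#' on negative IoU, gated at `iou_gate`.
#'
#' @param last_boxes matrix of the lost tracks' last observed boxes.
#' @param det_boxes matrix of leftover detection boxes.
#' @param iou_gate minimum IoU for a feasible pairing.
#' @return association result as in [solve_assignment()].
#' @export
ocr_associate <- function(last_boxes, det_boxes, iou_gate = 0.3) {
  ious <- iou_matrix(last_boxes, det_boxes)
  solve_assignment(list(values = -ious, feasible = ious >= iou_gate))
}
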