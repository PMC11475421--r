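# Per-frame tracking orchestration: predict -> primary association (with
# direction-consistency cost) -> OCR recovery -> update / ORU re-update ->
# track lifecycle (creation at high confidence, retention while untracked,
# deletion after max_age missed frames).

#' Tracker configuration
#'
#' All tunable tracking parameters with their defaults. `max_age` (30
#' frames) and `new_track_confidence` (0.7) are the published operating
#' points of the tracker; the association weights (`lambda_weight`,
#' `delta_t`, `iou_gate`) follow the observation-centric tracker family's
#' conventional defaults. `enable_ocr` / `enable_oru` switch the two
#' occlusion-recovery mechanisms off for ablation.
#'
#' @param max_age maximum number of consecutive unmatched frames before a
#'   track is deleted.
#' @param new_track_confidence minimum detection confidence to start a new
#'   track from an unmatched detection.
#' @param lambda_weight weight of the direction-consistency cost term.
#' @param delta_t momentum horizon (frames) for the direction term.
#' @param iou_gate minimum IoU for a feasible association (primary and OCR).
#' @param min_hits matched frames required before a track emits output
#'   (default 1: tracks are emitted from their first frame).
#' @param enable_ocr run the second-stage recovery association.
#' @param enable_oru re-update the filter along a virtual trajectory after
#'   an occlusion gap.
#' @param r_diag,q_diag,p_pos,p_vel Kalman noise model, see [kf_model()] and
#'   [kf_init()].
#' @return a `tracker_config` list.
#' @export
tracker_config <- function(max_age = 30L,
                           new_track_confidence = 0.7,
                           lambda_weight = 0.2,
                           delta_t = 3L,
                           iou_gate = 0.3,
                           min_hits = 1L,
                           enable_ocr = TRUE,
                           enable_oru = TRUE,
                           r_diag = c(1, 1, 10, 10),
                           q_diag = c(1, 1, 1, 0.01, 0.01, 0.01, 1e-4),
                           p_pos = 10,
                           p_vel = 1e4) {
  stopifnot(max_age >= 1, new_track_confidence >= 0, new_track_confidence <= 1,
            iou_gate >= 0, iou_gate <= 1, delta_t >= 1, min_hits >= 1)
  structure(list(max_age = as.integer(max_age),
                 new_track_confidence = new_track_confidence,
                 lambda_weight = lambda_weight,
                 delta_t = as.integer(delta_t),
                 iou_gate = iou_gate,
                 min_hits = as.integer(min_hits),
                 enable_ocr = isTRUE(enable_ocr),
                 enable_oru = isTRUE(enable_oru),
                 r_diag = r_diag, q_diag = q_diag,
                 p_pos = p_pos, p_vel = p_vel),
            class = "tracker_config")
}

#' Create a tracker
#'
#' Returns a mutable tracker object (an environment) to be advanced one
#' frame at a time with [tracker_step()], or driven over a whole detection
#' table with [track_sequence()].
#'
#' @param config a [tracker_config()].
#' @return object of class `pig_tracker`.
#' @export
pig_tracker <- function(config = tracker_config()) {
  tr <- new.env(parent = emptyenv())
  tr$config <- config
  tr$model <- kf_model(config$r_diag, config$q_diag)
  tr$tracks <- list()
  tr$archive <- list()   # summaries of deleted tracks (behaviour accounting)
  tr$next_id <- 1L
  tr$last_frame <- 0L
  class(tr) <- "pig_tracker"
  tr
}

.new_track <- function(tracker, frame, det_row) {
  cfg <- tracker$config
  box <- as.numeric(det_row[c("left", "top", "width", "height")])
  z <- box_to_obs(box)
  kf <- kf_init(z, cfg$p_pos, cfg$p_vel)
  counts <- behavior_increment(rep(0L, 4L), det_row$behavior)
  list(id = tracker$next_id,
       kf = kf,
       kf_post = kf,
       history = data.frame(frame = frame, u = z[["u"]], v = z[["v"]]),
       last_obs = unname(z),
       last_box = box,
       last_observed_frame = frame,
       time_since_update = 0L,
       status = "active",
       hits = 1L,
       behavior_counts = counts,
       last_behavior = det_row$behavior)
}

.match_track <- function(track, frame, det_row, tracker) {
  cfg <- tracker$config
  box <- as.numeric(det_row[c("left", "top", "width", "height")])
  z <- box_to_obs(box)
  gap <- frame - track$last_observed_frame
  if (gap >= 2L && cfg$enable_oru) {
    virtual <- make_virtual_trajectory(track$last_obs, z,
                                       track$last_observed_frame, frame)
    track$kf <- kf_re_update(track$kf_post, virtual, z, tracker$model)
  } else {
    track$kf <- kf_update(track$kf, z, tracker$model)
  }
  track$kf_post <- track$kf
  track$history <- rbind(track$history,
                         data.frame(frame = frame, u = z[["u"]], v = z[["v"]]))
  track$last_obs <- unname(z)
  track$last_box <- box
  track$last_observed_frame <- frame
  track$time_since_update <- 0L
  track$status <- "active"
  track$hits <- track$hits + 1L
  track$behavior_counts <- behavior_increment(track$behavior_counts,
                                              det_row$behavior)
  track$last_behavior <- det_row$behavior
  track
}

.empty_output <- function() {
  data.frame(frame = integer(0), id = integer(0), left = numeric(0),
             top = numeric(0), width = numeric(0), height = numeric(0),
             conf = numeric(0), class = integer(0), behavior = character(0))
}

#' Advance the tracker by one frame
#'
#' Runs the full per-frame cycle: predict all live tracks, primary
#' association of predicted boxes against the frame's detections (IoU +
#' direction-consistency cost), OCR second-stage association of the
#' leftovers on last observed boxes, filter update (with ORU re-update when
#' a track returns after a gap of two or more frames), creation of new
#' tracks from confident unmatched detections, and deletion of tracks
#' unmatched for more than `max_age` frames. Frames must be presented in
#' strictly increasing order; empty frames (zero-row `detections`) are valid
#' and advance the clock.
#'
#' @param tracker a [pig_tracker()].
#' @param frame integer frame index.
#' @param detections data.frame of this frame's detections with columns
#'   `left`, `top`, `width`, `height`, `conf`, `behavior`.
#' @return data.frame of output rows (frame, id, box, conf = 1, class,
#'   behavior), one per track matched in this frame.
#' @export
tracker_step <- function(tracker, frame, detections) {
  cfg <- tracker$config
  frame <- as.integer(frame)
  if (frame <= tracker$last_frame) {
    stop("frames must be presented in strictly increasing order (got ", frame,
         " after ", tracker$last_frame, ")", call. = FALSE)
  }
  tracker$last_frame <- frame
  detections <- as.data.frame(detections)
  n_det <- nrow(detections)
  tracks <- tracker$tracks
  n_trk <- length(tracks)

  # (a) predict every live track
  for (i in seq_len(n_trk)) {
    tracks[[i]]$kf <- kf_predict(tracks[[i]]$kf, tracker$model)
  }

  det_boxes <- if (n_det) {
    as.matrix(detections[, c("left", "top", "width", "height")])
  } else matrix(numeric(0), 0, 4)

  # (b) primary association on predicted boxes
  if (n_trk && n_det) {
    track_boxes <- do.call(rbind, lapply(tracks, function(t) kf_predicted_box(t$kf)))
    histories <- lapply(tracks, `[[`, "history")
    cost <- build_cost(track_boxes, histories, det_boxes,
                       cfg$lambda_weight, cfg$delta_t, cfg$iou_gate)
    res <- solve_assignment(cost)
  } else {
    res <- list(matches = matrix(integer(0), 0, 2),
                unmatched_tracks = seq_len(n_trk),
                unmatched_detections = seq_len(n_det))
  }
  matches <- res$matches
  un_trk <- res$unmatched_tracks
  un_det <- res$unmatched_detections

  # (c) OCR: lost tracks' last observed boxes vs leftover detections
  if (cfg$enable_ocr && length(un_trk) && length(un_det)) {
    last_boxes <- do.call(rbind, lapply(tracks[un_trk], `[[`, "last_box"))
    res2 <- ocr_associate(last_boxes, det_boxes[un_det, , drop = FALSE],
                          cfg$iou_gate)
    if (nrow(res2$matches)) {
      extra <- cbind(un_trk[res2$matches[, 1]], un_det[res2$matches[, 2]])
      matches <- rbind(matches, extra)
      un_trk <- un_trk[res2$unmatched_tracks]
      un_det <- un_det[res2$unmatched_detections]
    }
  }

  out <- .empty_output()

  # (d) update matched tracks (ORU across gaps), accumulate behaviour
  if (nrow(matches)) {
    for (k in seq_len(nrow(matches))) {
      i <- matches[k, 1]; j <- matches[k, 2]
      tracks[[i]] <- .match_track(tracks[[i]], frame, detections[j, ], tracker)
      if (tracks[[i]]$hits >= cfg$min_hits) {
        out <- rbind(out, data.frame(
          frame = frame, id = tracks[[i]]$id,
          left = detections$left[j], top = detections$top[j],
          width = detections$width[j], height = detections$height[j],
          conf = 1,
          class = match(detections$behavior[j], behavior_levels()),
          behavior = detections$behavior[j]))
      }
    }
  }

  # (e) births from confident unmatched detections
  for (j in un_det) {
    if (detections$conf[j] >= cfg$new_track_confidence) {
      trk <- .new_track(tracker, frame, detections[j, ])
      tracker$next_id <- tracker$next_id + 1L
      tracks[[length(tracks) + 1L]] <- trk
      if (trk$hits >= cfg$min_hits) {
        out <- rbind(out, data.frame(
          frame = frame, id = trk$id,
          left = detections$left[j], top = detections$top[j],
          width = detections$width[j], height = detections$height[j],
          conf = 1,
          class = match(detections$behavior[j], behavior_levels()),
          behavior = detections$behavior[j]))
      }
    }
  }

  # (f) unmatched tracks stay untracked; stale ones are deleted
  keep <- rep(TRUE, length(tracks))
  for (i in un_trk) {
    tracks[[i]]$time_since_update <- frame - tracks[[i]]$last_observed_frame
    tracks[[i]]$status <- "untracked"
    if (tracks[[i]]$time_since_update > cfg$max_age) {
      tracks[[i]]$status <- "deleted"
      tracker$archive[[length(tracker$archive) + 1L]] <-
        .track_summary(tracks[[i]])
      keep[i] <- FALSE
    }
  }
  tracker$tracks <- tracks[keep]

  if (nrow(out)) out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.track_summary <- function(track) {
  list(id = track$id,
       behavior_counts = track$behavior_counts,
       n_observations = nrow(track$history),
       first_frame = track$history$frame[1],
       last_observed_frame = track$last_observed_frame,
       status = track$status)
}

#' Track a whole detection stream
#'
#' Drives [tracker_step()] over every frame from 1 to the last detection
#' frame (frames without detections are stepped as empty). Deterministic:
#' identical input and config give byte-identical output.
#'
#' @param detections detection table from [read_detections()] (or the
#'   simulator).
#' @param config a [tracker_config()].
#' @param n_frames optional number of frames to process; defaults to the
#'   largest detection frame.
#' @return list of class `pigtrack_result` with `track_table` (all emitted
#'   rows), `tracks` (per-track summaries: id, behaviour frame counts,
#'   number of observations, lifecycle status) and `config`.
#' @export
track_sequence <- function(detections, config = tracker_config(),
                           n_frames = NULL) {
  if (is.null(n_frames)) {
    n_frames <- if (nrow(detections)) max(detections$frame) else 0L
  }
  tracker <- pig_tracker(config)
  pieces <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    dets_f <- detections[detections$frame == f, , drop = FALSE]
    pieces[[f]] <- tracker_step(tracker, f, dets_f)
  }
  table <- if (n_frames) do.call(rbind, pieces) else .empty_output()
  rownames(table) <- NULL
  summaries <- c(tracker$archive, lapply(tracker$tracks, .track_summary))
  ids <- vapply(summaries, `[[`, integer(1), "id")
  summaries <- summaries[order(ids)]
  structure(list(track_table = table, tracks = summaries, config = config),
            class = "pigtrack_result")
}

#' @export
print.pigtrack_result <- function(x, ...) {
  cat("pigtrack result:", length(x$tracks), "tracks,",
      nrow(x$track_table), "output rows over",
      if (nrow(x$track_table)) max(x$track_table$frame) else 0, "frames\n")
  invisible(x)
}
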