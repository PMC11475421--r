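# Behaviour time accounting: each track carries a frame-count vector
# [A1, A2, A3, A4] over (lie, stand, eat, other). Every matched detection
# adds an indicator vector with a single 1 at its class; durations are
# counts / fps and the herd time budget pools counts over all tracks.

#' Increment a behaviour frame-count vector
#'
#' Adds the indicator of `behavior` to the 4-vector of cumulative frame
#' counts: exactly one entry grows by 1.
#'
#' @param counts integer 4-vector `[A1, A2, A3, A4]` over
#'   (lie, stand, eat, other).
#' @param behavior one of `behavior_levels()`.
#' @return updated counts.
#' @export
behavior_increment <- function(counts, behavior) {
  k <- match(behavior, behavior_levels())
  if (is.na(k)) {
    stop("unknown behavior class: ", format(behavior), call. = FALSE)
  }
  counts[k] <- counts[k] + 1L
  counts
}

#' Per-animal durations and herd time budget
#'
#' Converts accumulated behaviour frame counts to per-track durations in
#' seconds (`counts / fps`, exact) and a herd-level percentage per class
#' (frame-weighted pooling over all tracks: `100 * sum_k(counts_k) /
#' sum(all counts)`).
#'
#' @param result a `pigtrack_result` from [track_sequence()], or a list of
#'   per-track summaries each holding `id` and `behavior_counts`.
#' @param fps frames per second of the sequence (recordings are annotated at
#'   5 fps).
#' @return list of class `behavior_report`: `per_track` data.frame (id, the
#'   four counts, the four durations `*_s` in seconds, total frames),
#'   `herd_percent` named numeric summing to 100 (or `NULL` when no frames
#'   were accumulated), `fps`.
#' @export
behavior_report <- function(result, fps = 5) {
  stopifnot(fps > 0)
  tracks <- if (inherits(result, "pigtrack_result")) result$tracks else result
  lv <- behavior_levels()
  n <- length(tracks)
  counts <- matrix(0L, n, 4, dimnames = list(NULL, lv))
  ids <- integer(n)
  for (i in seq_len(n)) {
    ids[i] <- tracks[[i]]$id
    counts[i, ] <- tracks[[i]]$behavior_counts
  }
  dur <- counts / fps
  colnames(dur) <- paste0(lv, "_s")
  per_track <- data.frame(id = ids, counts, dur,
                          total_frames = rowSums(counts))
  per_track <- per_track[order(per_track$id), , drop = FALSE]
  rownames(per_track) <- NULL
  total <- sum(counts)
  herd <- if (total > 0) {
    100 * colSums(counts) / total
  } else NULL
  structure(list(per_track = per_track, herd_percent = herd, fps = fps),
            class = "behavior_report")
}

#' @export
print.behavior_report <- function(x, ...) {
  cat("behaviour time budget over", nrow(x$per_track), "tracks at",
      x$fps, "fps\n")
  if (is.null(x$herd_percent)) {
    cat("  no accumulated frames; herd percentages undefined\n")
  } else {
    cat("  herd:", paste(sprintf("%s %.2f%%", names(x$herd_percent),
                                 x$herd_percent), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Behaviour report from an emitted track table
#'
#' Rebuilds per-track behaviour frame counts from the rows of a tracker
#' output table (each emitted row carries the matched detection's class) and
#' produces the same report as [behavior_report()]. This is what the
#' `analyze-behavior` CLI subcommand runs on an out.txt file.
#'
#' @param track_table data.frame with columns `id` and `behavior` (e.g. from
#'   [read_tracks()] or `track_sequence()$track_table`).
#' @param fps frames per second.
#' @return a `behavior_report`.
#' @export
behavior_report_from_table <- function(track_table, fps = 5) {
  lv <- behavior_levels()
  ids <- sort(unique(track_table$id))
  summaries <- lapply(ids, function(i) {
    beh <- track_table$behavior[track_table$id == i]
    list(id = i,
         behavior_counts = as.integer(table(factor(beh, levels = lv))))
  })
  behavior_report(summaries, fps)
}

#' Serialise a behaviour report to JSON
#'
#' @param report a [behavior_report()].
#' @param path output path for the JSON report.
#' @return `path`, invisibly.
#' @export
write_behavior_report <- function(report, path) {
  lv <- behavior_levels()
  per_track <- lapply(seq_len(nrow(report$per_track)), function(i) {
    row <- report$per_track[i, ]
    stats::setNames(as.list(as.numeric(row[paste0(lv, "_s")])),
                    paste0(lv, "_s"))
  })
  names(per_track) <- as.character(report$per_track$id)
  herd <- if (is.null(report$herd_percent)) NULL else as.list(report$herd_percent)
  jsonlite::write_json(list(fps = report$fps,
                            per_track = per_track,
                            herd_percent = herd),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
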