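# File dialect: comma-separated MOTChallenge-style rows
#   frame,id,left,top,width,height,confidence,class_index
# with class_index 1=lie, 2=stand, 3=eat, 4=other in column 8 (where the
# MOTChallenge gt dialect carries its class). Raw detections use id = -1.
# Frames are 1-based; boxes are (left, top, width, height) px, origin top-left.

#' Behaviour categories in canonical order
#'
#' The four behaviour classes, in the fixed array order used for the
#' per-track frame-count vector `[A1, A2, A3, A4]`: lie, stand, eat, other.
#'
#' @return character vector of length 4.
#' @export
behavior_levels <- function() c("lie", "stand", "eat", "other")

.parse_mot <- function(path, what = c("det", "gt")) {
  what <- match.arg(what)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  cols <- c("frame", "id", "left", "top", "width", "height", "conf", "class")
  if (length(lines) == 0L) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), 8L), cols))
    df$behavior <- character(0)
    return(df)
  }
  parts <- strsplit(lines, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 8L)
  if (length(bad)) {
    stop(sprintf("malformed row at line %d of %s: expected 8 comma-separated fields",
                 bad[1], path), call. = FALSE)
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 8L, byrow = TRUE)
  nas <- which(rowSums(is.na(m)) > 0L)
  if (length(nas)) {
    stop(sprintf("malformed row at line %d of %s: non-numeric field", nas[1], path),
         call. = FALSE)
  }
  df <- as.data.frame(m)
  names(df) <- cols
  if (any(df$class %% 1 != 0) || any(df$class < 1) || any(df$class > 4)) {
    bad <- which(df$class %% 1 != 0 | df$class < 1 | df$class > 4)[1]
    stop(sprintf("unknown class_index %s at line %d of %s (expected 1..4)",
                 format(df$class[bad]), bad, path), call. = FALSE)
  }
  if (any(df$width <= 0) || any(df$height <= 0)) {
    stop("invalid box: width and height must be positive in ", path, call. = FALSE)
  }
  df$frame <- as.integer(df$frame)
  df$id <- as.integer(df$id)
  df$class <- as.integer(df$class)
  df$behavior <- behavior_levels()[df$class]
  if (what == "det") {
    if (any(df$conf < 0 | df$conf > 1)) {
      stop("detection confidence outside [0, 1] in ", path, call. = FALSE)
    }
    # sorted by frame, then by descending confidence within the frame
    df <- df[order(df$frame, -df$conf), , drop = FALSE]
  } else {
    if (anyDuplicated(df[c("frame", "id")])) {
      stop("duplicate (frame, id) pair in ", path, call. = FALSE)
    }
    df <- df[order(df$frame, df$id), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Read raw detections
#'
#' Reads a detection file in the package's MOTChallenge-style dialect:
#' `frame,id,left,top,width,height,confidence,class_index` with `id = -1`
#' for raw detections and class_index 1..4 mapping to lie/stand/eat/other.
#'
#' @param path path to a detection text file.
#' @return data.frame with columns `frame`, `id`, `left`, `top`, `width`,
#'   `height`, `conf`, `class`, `behavior`, sorted by frame then by
#'   descending confidence within each frame. Frames with no rows are simply
#'   absent; [detections_by_frame()] reinstates them as empty groups.
#' @export
read_detections <- function(path) .parse_mot(path, "det")

#' Read a ground-truth or tracker-output track table
#'
#' Same dialect as [read_detections()] but ids must be assigned (positive)
#' and `(frame, id)` pairs unique within the sequence.
#'
#' @param path path to a gt.txt / out.txt style file.
#' @return data.frame as in [read_detections()], sorted by frame then id.
#' @export
read_tracks <- function(path) .parse_mot(path, "gt")

#' Write a track table (ground truth or tracker output)
#'
#' Writes rows in the dialect read back by [read_tracks()]; confidence is
#' fixed at 1 for outputs. Round-trips field-for-field.
#'
#' @param records data.frame with columns `frame`, `id`, `left`, `top`,
#'   `width`, `height` and either `class` (1..4) or `behavior`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records) && is.null(records$class)) {
    records$class <- match(records$behavior, behavior_levels())
  }
  if (nrow(records) && any(records$id <= 0)) {
    stop("track records must have assigned positive ids", call. = FALSE)
  }
  lines <- if (nrow(records)) {
    sprintf("%d,%d,%s,%s,%s,%s,1,%d",
            as.integer(records$frame), as.integer(records$id),
            .num(records$left), .num(records$top),
            .num(records$width), .num(records$height),
            as.integer(records$class))
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Write raw detections
#'
#' @param detections data.frame with columns `frame`, `left`, `top`, `width`,
#'   `height`, `conf` and either `class` or `behavior`; `id` is written as -1.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  detections <- as.data.frame(detections)
  if (nrow(detections) && is.null(detections$class)) {
    detections$class <- match(detections$behavior, behavior_levels())
  }
  lines <- if (nrow(detections)) {
    sprintf("%d,-1,%s,%s,%s,%s,%s,%d",
            as.integer(detections$frame),
            .num(detections$left), .num(detections$top),
            .num(detections$width), .num(detections$height),
            .num(detections$conf), as.integer(detections$class))
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}

# locale-independent numeric formatting: '.' decimal mark, full precision
.num <- function(x) {
  vapply(x, function(v) format(v, scientific = FALSE, trim = TRUE, digits = 15,
                               decimal.mark = "."), character(1))
}

#' Split a detection table into per-frame groups
#'
#' @param detections data.frame from [read_detections()].
#' @param frames optional integer vector of frame indices to cover; defaults
#'   to `1:max(frame)`. Frames with no detections yield empty groups.
#' @return named list, one data.frame per frame (possibly zero-row).
#' @export
detections_by_frame <- function(detections, frames = NULL) {
  if (is.null(frames)) {
    frames <- if (nrow(detections)) seq_len(max(detections$frame)) else integer(0)
  }
  out <- lapply(frames, function(f) detections[detections$frame == f, , drop = FALSE])
  names(out) <- as.character(frames)
  out
}
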