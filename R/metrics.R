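# Tracking evaluation: per-frame IoU matching, CLEAR-MOT accuracy (MOTA with
# identity switches), identity F1 over a global gt<->pred bijection, and
# HOTA (geometric mean of detection and association accuracy, averaged over
# localisation thresholds).

# Shared per-frame scaffolding: ids and the IoU matrix for every frame in
# the union of the two tables, computed once and re-gated per threshold.
.frame_data <- function(gt, pred) {
  frames <- sort(union(unique(gt$frame), unique(pred$frame)))
  gt_split <- split(gt, gt$frame)
  pred_split <- split(pred, pred$frame)
  lapply(frames, function(f) {
    g <- gt_split[[as.character(f)]]
    p <- pred_split[[as.character(f)]]
    gb <- if (is.null(g)) matrix(numeric(0), 0, 4) else
      as.matrix(g[, c("left", "top", "width", "height")])
    pb <- if (is.null(p)) matrix(numeric(0), 0, 4) else
      as.matrix(p[, c("left", "top", "width", "height")])
    list(frame = f,
         gt_ids = if (is.null(g)) integer(0) else g$id,
         pred_ids = if (is.null(p)) integer(0) else p$id,
         iou = iou_matrix(gb, pb))
  })
}

.match_at <- function(fd, alpha) {
  lapply(fd, function(x) {
    res <- solve_assignment(list(values = -x$iou, feasible = x$iou >= alpha))
    m <- res$matches
    list(frame = x$frame,
         tp = data.frame(gt_id = x$gt_ids[m[, 1]], pred_id = x$pred_ids[m[, 2]]),
         fn_ids = x$gt_ids[res$unmatched_tracks],
         fp_ids = x$pred_ids[res$unmatched_detections])
  })
}

#' Per-frame matching between ground truth and tracker output
#'
#' For each frame (union of the frames present in either table), solves a
#' minimum-cost bipartite matching on `1 - IoU` with pairs below the IoU
#' threshold forbidden; leftovers are false negatives / false positives.
#'
#' @param gt,pred track tables as returned by [read_tracks()] (columns
#'   `frame`, `id`, `left`, `top`, `width`, `height`).
#' @param alpha IoU threshold below which a gt/pred pair cannot match.
#' @return list with one element per frame: `frame`, `tp` (data.frame of
#'   matched `gt_id`, `pred_id` pairs), `fn_ids`, `fp_ids`.
#' @export
match_frames <- function(gt, pred, alpha = 0.5) {
  .match_at(.frame_data(gt, pred), alpha)
}

# CLEAR identity switches: a switch is counted whenever a gt identity's
# matched pred id differs from that identity's most recent previous match.
.count_ids <- function(matchings) {
  last <- new.env(parent = emptyenv())
  ids <- 0L
  for (m in matchings) {
    tp <- m$tp
    for (k in seq_len(nrow(tp))) {
      key <- as.character(tp$gt_id[k])
      prev <- if (exists(key, envir = last)) get(key, envir = last) else NA
      if (!is.na(prev) && prev != tp$pred_id[k]) ids <- ids + 1L
      assign(key, tp$pred_id[k], envir = last)
    }
  }
  ids
}

#' Multiple-object tracking accuracy (MOTA)
#'
#' `MOTA = 1 - (FP + FN + IDS) / total gt boxes`, with identity switches
#' counted by the CLEAR convention (a gt identity's matched pred id changes
#' between its consecutively matched frames). May be negative; undefined
#' (`NA`) when the ground truth is empty.
#'
#' @param matchings per-frame matchings from [match_frames()].
#' @param gt ground-truth track table.
#' @return list with `mota`, `fp`, `fn`, `ids`, `tp`, `gt_total`.
#' @export
mota_score <- function(matchings, gt) {
  fp <- sum(vapply(matchings, function(m) length(m$fp_ids), integer(1)))
  fn <- sum(vapply(matchings, function(m) length(m$fn_ids), integer(1)))
  tp <- sum(vapply(matchings, function(m) nrow(m$tp), integer(1)))
  ids <- .count_ids(matchings)
  gt_total <- nrow(gt)
  mota <- if (gt_total > 0) 1 - (fp + fn + ids) / gt_total else NA_real_
  list(mota = mota, fp = fp, fn = fn, ids = ids, tp = tp, gt_total = gt_total)
}

#' Identity F1 (IDF1)
#'
#' Chooses the global one-to-one gt-id/pred-id bijection that maximises the
#' number of correctly identified boxes (frames where the paired ids
#' co-occur with IoU at least `alpha`), then scores
#' `IDF1 = 2 IDTP / (2 IDTP + IDFP + IDFN)`.
#'
#' @param gt,pred track tables.
#' @param alpha IoU threshold for a box to count as correctly identified.
#' @return list with `idf1`, `idtp`, `idfp`, `idfn`.
#' @export
idf1_score <- function(gt, pred, alpha = 0.5) {
  gids <- sort(unique(gt$id)); pids <- sort(unique(pred$id))
  fd <- .frame_data(gt, pred)
  overlap <- matrix(0L, length(gids), length(pids),
                    dimnames = list(gids, pids))
  for (x in fd) {
    if (!length(x$gt_ids) || !length(x$pred_ids)) next
    hit <- which(x$iou >= alpha, arr.ind = TRUE)
    for (k in seq_len(nrow(hit))) {
      gi <- match(x$gt_ids[hit[k, 1]], gids)
      pj <- match(x$pred_ids[hit[k, 2]], pids)
      overlap[gi, pj] <- overlap[gi, pj] + 1L
    }
  }
  idtp <- 0L
  if (length(gids) && length(pids)) {
    assign <- solve_lap(-overlap)
    for (i in seq_along(assign)) {
      if (!is.na(assign[i])) idtp <- idtp + overlap[i, assign[i]]
    }
  }
  idfp <- nrow(pred) - idtp
  idfn <- nrow(gt) - idtp
  denom <- 2 * idtp + idfp + idfn
  idf1 <- if (denom > 0) 2 * idtp / denom else NA_real_
  list(idf1 = idf1, idtp = as.integer(idtp), idfp = as.integer(idfp),
       idfn = as.integer(idfn))
}

.hota_at <- function(fd, alpha) {
  matchings <- .match_at(fd, alpha)
  tp_pairs <- do.call(rbind, lapply(matchings, `[[`, "tp"))
  tp <- if (is.null(tp_pairs)) 0L else nrow(tp_pairs)
  fn <- sum(vapply(matchings, function(m) length(m$fn_ids), integer(1)))
  fp <- sum(vapply(matchings, function(m) length(m$fp_ids), integer(1)))
  if (tp + fn + fp == 0L) {
    return(list(hota = NA_real_, deta = NA_real_, assa = NA_real_,
                tp = 0L, fn = fn, fp = fp))
  }
  deta <- tp / (tp + fn + fp)
  if (tp == 0L) {
    return(list(hota = 0, deta = deta, assa = 0, tp = 0L, fn = fn, fp = fp))
  }
  # per-identity-pair association accuracy:
  # A(g,p) = TPA(g,p) / (|frames of g| + |frames of p| - TPA(g,p))
  gt_frames <- table(unlist(lapply(matchings, function(m)
    c(m$tp$gt_id, m$fn_ids))))
  pred_frames <- table(unlist(lapply(matchings, function(m)
    c(m$tp$pred_id, m$fp_ids))))
  key <- paste(tp_pairs$gt_id, tp_pairs$pred_id)
  tpa <- table(key)
  a_c <- vapply(seq_len(tp), function(k) {
    t_gp <- as.numeric(tpa[[key[k]]])
    g_n <- as.numeric(gt_frames[[as.character(tp_pairs$gt_id[k])]])
    p_n <- as.numeric(pred_frames[[as.character(tp_pairs$pred_id[k])]])
    t_gp / (g_n + p_n - t_gp)
  }, numeric(1))
  assa <- mean(a_c)
  list(hota = sqrt(deta * assa), deta = deta, assa = assa,
       tp = tp, fn = fn, fp = fp)
}

#' Higher-order tracking accuracy (HOTA)
#'
#' At each localisation threshold alpha, detection accuracy is
#' `DetA = TP / (TP + FN + FP)` over the per-frame matching, association
#' accuracy `AssA` is the mean over true-positive matches `c` with identity
#' pair `(g, p)` of `A(c) = TPA / (|frames of g| + |frames of p| - TPA)`,
#' and `HOTA_alpha = sqrt(DetA * AssA)`. The headline score averages
#' `HOTA_alpha` over `alphas` (canonically 0.05, 0.10, ..., 0.95); pass a
#' single value to get the single-threshold variant.
#'
#' @param gt,pred track tables.
#' @param alphas vector of IoU thresholds.
#' @return list with `hota`, `deta`, `assa` (means over `alphas`) and
#'   `per_alpha` (data.frame of the per-threshold values and counts).
#' @export
hota_score <- function(gt, pred, alphas = seq(0.05, 0.95, by = 0.05)) {
  fd <- .frame_data(gt, pred)
  rows <- lapply(alphas, function(a) {
    h <- .hota_at(fd, a)
    data.frame(alpha = a, hota = h$hota, deta = h$deta, assa = h$assa,
               tp = h$tp, fn = h$fn, fp = h$fp)
  })
  per_alpha <- do.call(rbind, rows)
  list(hota = mean(per_alpha$hota), deta = mean(per_alpha$deta),
       assa = mean(per_alpha$assa), per_alpha = per_alpha)
}

#' Evaluate tracker output against ground truth
#'
#' Full evaluation report: HOTA/DetA/AssA (threshold-averaged, plus the
#' single-threshold value at `iou_threshold`), MOTA with its FP/FN/IDS
#' decomposition, and IDF1 with its IDTP/IDFP/IDFN decomposition. When the
#' two tables cover different frame ranges a warning is issued and the union
#' of frames is evaluated.
#'
#' @param gt,pred track tables (see [read_tracks()]).
#' @param iou_threshold IoU threshold for MOTA/IDF1 matching and for the
#'   single-threshold HOTA.
#' @param hota_alphas thresholds averaged for the headline HOTA.
#' @return list of class `metrics_report`.
#' @export
evaluate_tracking <- function(gt, pred, iou_threshold = 0.5,
                              hota_alphas = seq(0.05, 0.95, by = 0.05)) {
  if (nrow(gt) && nrow(pred) &&
      (min(gt$frame) != min(pred$frame) || max(gt$frame) != max(pred$frame))) {
    warning("gt and prediction cover different frame ranges; ",
            "evaluating over the union of frames")
  }
  matchings <- match_frames(gt, pred, iou_threshold)
  clear <- mota_score(matchings, gt)
  idm <- idf1_score(gt, pred, iou_threshold)
  h <- hota_score(gt, pred, hota_alphas)
  h1 <- hota_score(gt, pred, iou_threshold)
  structure(list(hota = h$hota, deta = h$deta, assa = h$assa,
                 hota_single = h1$hota, deta_single = h1$deta,
                 assa_single = h1$assa,
                 mota = clear$mota, idf1 = idm$idf1,
                 ids = clear$ids, fp = clear$fp, fn = clear$fn,
                 tp = clear$tp, gt_total = clear$gt_total,
                 idtp = idm$idtp, idfp = idm$idfp, idfn = idm$idfn,
                 iou_threshold = iou_threshold,
                 per_alpha = h$per_alpha),
            class = "metrics_report")
}

#' Evaluate from files
#'
#' @param gt_path,pred_path paths to gt.txt / out.txt style files.
#' @param ... passed to [evaluate_tracking()].
#' @return a `metrics_report`.
#' @export
evaluate_files <- function(gt_path, pred_path, ...) {
  evaluate_tracking(read_tracks(gt_path), read_tracks(pred_path), ...)
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
  cat("tracking evaluation (IoU threshold ", x$iou_threshold, ")\n", sep = "")
  cat("  HOTA ", fmt(x$hota), " (DetA ", fmt(x$deta), ", AssA ", fmt(x$assa),
      "; single-threshold ", fmt(x$hota_single), ")\n", sep = "")
  cat("  MOTA ", fmt(x$mota), "  IDF1 ", fmt(x$idf1), "\n", sep = "")
  cat("  IDS ", x$ids, "  FP ", x$fp, "  FN ", x$fn, "  (gt boxes ",
      x$gt_total, ")\n", sep = "")
  invisible(x)
}

#' Serialise a metrics report to JSON
#'
#' @param report a `metrics_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  flat <- report[c("hota", "deta", "assa", "hota_single", "mota", "idf1",
                   "ids", "fp", "fn", "tp", "gt_total",
                   "idtp", "idfp", "idfn", "iou_threshold")]
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
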