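# Shared independent oracles and fixture builders. Everything here is
# deliberately brute-force and separate from the package's own code paths.

# Exhaustive minimum-cost assignment: enumerate every injective mapping of
# rows to columns over feasible cells, preferring maximum cardinality and,
# within that, minimum total cost. Feasible for max(N, M) <= 6.
oracle_assignment <- function(values, feasible = NULL) {
  n <- nrow(values); m <- ncol(values)
  if (is.null(feasible)) feasible <- matrix(TRUE, n, m)
  best <- list(card = -1L, cost = Inf, matches = NULL)
  recurse <- function(i, used_cols, matches, cost) {
    if (i > n) {
      card <- nrow(matches)
      if (card > best$card ||
          (card == best$card && cost < best$cost - 1e-12)) {
        best <<- list(card = card, cost = cost, matches = matches)
      }
      return(invisible())
    }
    recurse(i + 1L, used_cols, matches, cost)  # row i unmatched
    for (j in seq_len(m)) {
      if (!used_cols[j] && feasible[i, j]) {
        used_cols[j] <- TRUE
        recurse(i + 1L, used_cols, rbind(matches, c(i, j)),
                cost + values[i, j])
        used_cols[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, m), matrix(integer(0), 0, 2), 0)
  best
}

# Independent IoU: interval-overlap arithmetic written out separately.
oracle_iou <- function(a, b) {
  x1 <- max(a[1], b[1]); x2 <- min(a[1] + a[3], b[1] + b[3])
  y1 <- max(a[2], b[2]); y2 <- min(a[2] + a[4], b[2] + b[4])
  inter <- max(0, x2 - x1) * max(0, y2 - y1)
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

# Exhaustive IDF1: try every injective gt-id -> pred-id mapping, maximising
# the number of frames where the paired ids co-occur with IoU >= alpha.
oracle_idf1 <- function(gt, pred, alpha = 0.5) {
  gids <- sort(unique(gt$id)); pids <- sort(unique(pred$id))
  overlap <- matrix(0L, length(gids), length(pids))
  for (f in union(gt$frame, pred$frame)) {
    g <- gt[gt$frame == f, ]; p <- pred[pred$frame == f, ]
    for (i in seq_len(nrow(g))) for (j in seq_len(nrow(p))) {
      if (oracle_iou(as.numeric(g[i, c("left", "top", "width", "height")]),
                     as.numeric(p[j, c("left", "top", "width", "height")]))
          >= alpha) {
        gi <- match(g$id[i], gids); pj <- match(p$id[j], pids)
        overlap[gi, pj] <- overlap[gi, pj] + 1L
      }
    }
  }
  best <- oracle_assignment(-overlap)
  idtp <- if (nrow(best$matches)) {
    sum(overlap[best$matches])
  } else 0L
  2 * idtp / (2 * idtp + (nrow(pred) - idtp) + (nrow(gt) - idtp))
}

# A single constant-velocity pig crossing the pen with one detection gap:
# the fixture for the occlusion-recovery study. Behaviour (hence speed) is
# lie-dominated as in a real herd; the track is lost h frames after birth
# for g frames, with 10 post-gap frames and 1.5 px detection noise.
make_gap_scenario <- function(seed, gap = NULL) {
  set.seed(seed)
  lv <- behavior_levels()
  beh <- sample(1:4, 1, prob = c(0.6, 0.15, 0.15, 0.10))
  speed <- c(0, 1.2, 0.4, 2.5)[beh]
  heading <- runif(1, 0, 2 * pi)
  h <- sample(2:5, 1)
  g <- if (is.null(gap)) sample(2:30, 1) else gap
  n <- h + g + 10L
  t <- seq_len(n)
  cx <- 640 + speed * cos(heading) * (t - 1)
  cy <- 360 + speed * sin(heading) * (t - 1)
  gt <- data.frame(frame = t, id = 1L, left = cx - 55, top = cy - 32.5,
                   width = 110, height = 65, conf = 1, class = beh,
                   behavior = lv[beh])
  det <- gt[!(gt$frame %in% (h + 1):(h + g)), ]
  det$left <- det$left + rnorm(nrow(det), 0, 1.5)
  det$top <- det$top + rnorm(nrow(det), 0, 1.5)
  det$width <- pmax(det$width + rnorm(nrow(det), 0, 1.5), 5)
  det$height <- pmax(det$height + rnorm(nrow(det), 0, 1.5), 5)
  det$id <- -1L
  det$conf <- 0.95
  list(gt = gt, det = det, pre_gap = h, gap = g)
}

# TRUE if one single track spans the whole scenario under `config`.
keeps_identity <- function(det, config) {
  tt <- track_sequence(det, config)$track_table
  nrow(tt) > 0 && length(unique(tt$id)) == 1L
}

# Well-separated two-track ground truth used by several metric fixtures.
make_two_track_gt <- function(n_frames = 50) {
  rbind(
    data.frame(frame = seq_len(n_frames), id = 1L, left = 100, top = 100,
               width = 100, height = 60, conf = 1, class = 1L,
               behavior = "lie"),
    data.frame(frame = seq_len(n_frames), id = 2L, left = 600, top = 400,
               width = 100, height = 60, conf = 1, class = 2L,
               behavior = "stand"))
}
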