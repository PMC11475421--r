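# Synthetic pen simulator: behaviour-driven pig motion plus a detection
# degradation stage (noise, misses, occlusion dropouts, false positives),
# giving the tracker, behaviour and metrics modules fully controlled inputs
# with known ground truth and exactly known injected corruption.

#' Scene configuration for the pen simulator
#'
#' The defaults describe a "day, sparse-occlusion, medium-activity" pen of
#' the kind the tracker targets: 8 pigs in a 1280x720 px overhead view at
#' 5 fps, a behaviour Markov chain whose stationary distribution matches a
#' healthy lie-dominated herd time budget (~72/17/10/1% over
#' lie/stand/eat/other), behaviour-dependent speeds (lying pigs do not move,
#' eating pigs shuffle near the feeder, standing/other pigs walk), ~1 px
#' detection noise and low miss/false-positive rates. [scene_regime()]
#' derives night/dense/low- and high-activity variants.
#'
#' @param n_pigs number of pigs in the pen (typical pens hold 6-16).
#' @param fps frames per second (recordings are annotated at 5 fps).
#' @param duration_s scene length in seconds.
#' @param pen_width,pen_height pen size in pixels.
#' @param behavior_transition 4x4 row-stochastic per-frame transition matrix
#'   over (lie, stand, eat, other).
#' @param speed_by_behavior named px/frame speeds for the four behaviours.
#' @param turn_sd heading random-walk standard deviation (radians/frame).
#' @param body_length,body_width mean pig body axes in px (axis-aligned
#'   boxes change size with heading, exercising the area/aspect dynamics).
#' @param min_separation_px minimum centre separation enforced between pigs
#'   (animals are solid: boxes may overlap but never coincide).
#' @param occlusion_rate per-pig per-frame probability that a dropout starts.
#' @param occlusion_len mean dropout length in frames (geometric).
#' @param det_noise_px Gaussian std of detection noise on box centre and size.
#' @param fp_rate expected false positives per frame (Poisson).
#' @param miss_rate per-visible-pig per-frame miss probability.
#' @param conf_true_mean,conf_true_sd,conf_false_mean,conf_false_sd
#'   confidence model for true and false detections (clamped to (0, 1]).
#' @param seed integer seed fixing the full stream.
#' @return a `scene_config` list.
#' @export
scene_config <- function(n_pigs = 8L,
                         fps = 5,
                         duration_s = 60,
                         pen_width = 1280,
                         pen_height = 720,
                         behavior_transition = NULL,
                         speed_by_behavior = c(lie = 0, stand = 3,
                                               eat = 0.5, other = 5),
                         turn_sd = 0.3,
                         body_length = 110,
                         body_width = 65,
                         min_separation_px = 70,
                         occlusion_rate = 0.002,
                         occlusion_len = 5,
                         det_noise_px = 1,
                         fp_rate = 0.05,
                         miss_rate = 0.01,
                         conf_true_mean = 0.92, conf_true_sd = 0.03,
                         conf_false_mean = 0.5, conf_false_sd = 0.1,
                         seed = 1L) {
  if (is.null(behavior_transition)) {
    behavior_transition <- behavior_markov(c(0.72, 0.17, 0.10, 0.01))
  }
  stopifnot(n_pigs >= 1, fps > 0, duration_s > 0,
            nrow(behavior_transition) == 4, ncol(behavior_transition) == 4,
            all(behavior_transition >= 0),
            max(abs(rowSums(behavior_transition) - 1)) < 1e-9,
            all(c(occlusion_rate, miss_rate) >= 0),
            all(c(occlusion_rate, miss_rate) <= 1),
            fp_rate >= 0, det_noise_px >= 0, occlusion_len >= 1)
  cells <- floor(pen_width / (body_length + 30)) *
    floor(pen_height / (body_length + 30))
  if (cells < n_pigs) {
    stop(n_pigs, " pigs cannot fit a ", pen_width, "x", pen_height,
         " px pen at body length ", body_length, " px", call. = FALSE)
  }
  structure(list(n_pigs = as.integer(n_pigs), fps = fps,
                 duration_s = duration_s,
                 pen_width = pen_width, pen_height = pen_height,
                 behavior_transition = behavior_transition,
                 speed_by_behavior = speed_by_behavior,
                 turn_sd = turn_sd,
                 body_length = body_length, body_width = body_width,
                 min_separation_px = min_separation_px,
                 occlusion_rate = occlusion_rate,
                 occlusion_len = occlusion_len,
                 det_noise_px = det_noise_px, fp_rate = fp_rate,
                 miss_rate = miss_rate,
                 conf_true_mean = conf_true_mean, conf_true_sd = conf_true_sd,
                 conf_false_mean = conf_false_mean,
                 conf_false_sd = conf_false_sd,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Behaviour transition matrix with a prescribed time budget
#'
#' Builds the per-frame Markov matrix `(1 - leave) I + leave * 1 pi^T`: each
#' frame the pig keeps its behaviour with probability `1 - leave`, otherwise
#' redraws from `pi`. The chain's stationary distribution is exactly `pi`,
#' and `1 / leave` frames is the mean dwell time.
#'
#' @param pi length-4 stationary distribution over (lie, stand, eat, other).
#' @param leave per-frame probability of redrawing the behaviour.
#' @return 4x4 row-stochastic matrix.
#' @export
behavior_markov <- function(pi = c(0.72, 0.17, 0.10, 0.01), leave = 0.02) {
  stopifnot(length(pi) == 4, all(pi >= 0), abs(sum(pi) - 1) < 1e-9,
            leave > 0, leave <= 1)
  (1 - leave) * diag(4) + leave * matrix(pi, 4, 4, byrow = TRUE)
}

#' Preset scene regimes
#'
#' Variants of [scene_config()] along the axes on which recording conditions
#' differ: lighting (night raises detection noise and miss rate), occlusion
#' density (dense pens drop detections more often and for longer) and
#' activity level (more standing/walking time and faster movement).
#'
#' @param lighting `"day"` or `"night"`.
#' @param density `"sparse"` or `"dense"` occlusion regime.
#' @param activity `"L"`, `"M"` or `"H"`.
#' @param ... passed on to [scene_config()] (e.g. `n_pigs`, `seed`).
#' @return a `scene_config`.
#' @export
scene_regime <- function(lighting = c("day", "night"),
                         density = c("sparse", "dense"),
                         activity = c("M", "L", "H"), ...) {
  lighting <- match.arg(lighting)
  density <- match.arg(density)
  activity <- match.arg(activity)
  pi <- switch(activity,
               L = c(0.85, 0.08, 0.06, 0.01),
               M = c(0.72, 0.17, 0.10, 0.01),
               H = c(0.45, 0.28, 0.15, 0.12))
  speed_mult <- switch(activity, L = 0.7, M = 1, H = 1.5)
  scene_config(
    behavior_transition = behavior_markov(pi),
    speed_by_behavior = c(lie = 0, stand = 3, eat = 0.5, other = 5) * speed_mult,
    det_noise_px = if (lighting == "day") 1 else 2.5,
    miss_rate = if (lighting == "day") 0.01 else 0.04,
    occlusion_rate = if (density == "sparse") 0.002 else 0.01,
    occlusion_len = if (density == "sparse") 5 else 10,
    ...)
}

# axis-aligned box of an oriented pig body
.pig_box <- function(x, y, len, wid, heading) {
  w <- abs(len * cos(heading)) + abs(wid * sin(heading))
  h <- abs(len * sin(heading)) + abs(wid * cos(heading))
  c(left = x - w / 2, top = y - h / 2, width = w, height = h)
}

#' Generate a synthetic pen scene
#'
#' Pigs follow behaviour-dependent bounded random walks with direction
#' persistence (headings reflect at the pen walls, producing nonlinear
#' motion events by design); behaviour states evolve by the configured
#' Markov chain; eating pigs drift toward a feeder on the top wall. The
#' ground-truth boxes are then passed through [degrade_detections()].
#' The seed in `config` fixes the entire stream.
#'
#' @param config a [scene_config()].
#' @return list with `gt` (ground-truth track table), `detections` (degraded
#'   detection table, with the injected-corruption counts as attribute
#'   `injected`), `behavior_truth` (per-pig true behaviour frame counts) and
#'   `config`.
#' @export
generate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  n <- config$n_pigs
  n_frames <- as.integer(round(config$fps * config$duration_s))
  lv <- behavior_levels()
  P <- config$behavior_transition
  margin <- config$body_length / 2 + 1
  lo_x <- margin; hi_x <- config$pen_width - margin
  lo_y <- margin; hi_y <- config$pen_height - margin
  feeder <- c(config$pen_width / 2, lo_y)

  # jittered-grid initial placement keeps starting positions distinct
  ncol_grid <- ceiling(sqrt(n * config$pen_width / config$pen_height))
  nrow_grid <- ceiling(n / ncol_grid)
  gx <- seq(lo_x, hi_x, length.out = ncol_grid + 2)[2:(ncol_grid + 1)]
  gy <- seq(lo_y, hi_y, length.out = nrow_grid + 2)[2:(nrow_grid + 1)]
  grid <- expand.grid(x = gx, y = gy)[seq_len(n), ]
  x <- grid$x + stats::runif(n, -15, 15)
  y <- grid$y + stats::runif(n, -15, 15)
  heading <- stats::runif(n, 0, 2 * pi)
  len <- pmax(stats::rnorm(n, config$body_length, 8), 60)
  wid <- pmax(stats::rnorm(n, config$body_width, 5), 35)
  beh <- sample.int(4L, n, replace = TRUE,
                    prob = colMeans(P %*% P %*% P))  # near-stationary start

  rows <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    beh <- vapply(beh, function(b) sample.int(4L, 1L, prob = P[b, ]), integer(1))
    heading <- heading + stats::rnorm(n, 0, config$turn_sd)
    # eating pigs orient toward the feeder
    to_feeder <- atan2(feeder[2] - y, feeder[1] - x)
    eat <- beh == 3L
    heading[eat] <- 0.8 * heading[eat] + 0.2 * to_feeder[eat]
    sp <- config$speed_by_behavior[lv[beh]]
    x <- x + sp * cos(heading)
    y <- y + sp * sin(heading)
    # reflect at the walls
    bounce_x <- x < lo_x | x > hi_x
    x[x < lo_x] <- 2 * lo_x - x[x < lo_x]
    x[x > hi_x] <- 2 * hi_x - x[x > hi_x]
    heading[bounce_x] <- pi - heading[bounce_x]
    bounce_y <- y < lo_y | y > hi_y
    y[y < lo_y] <- 2 * lo_y - y[y < lo_y]
    y[y > hi_y] <- 2 * hi_y - y[y > hi_y]
    heading[bounce_y] <- -heading[bounce_y]
    # solid bodies: push too-close pairs apart
    if (n > 1L) {
      for (rep in 1:2) {
        for (i in 1:(n - 1)) for (j in (i + 1):n) {
          dx <- x[j] - x[i]; dy <- y[j] - y[i]
          d <- sqrt(dx^2 + dy^2)
          if (d < config$min_separation_px) {
            if (d < 1e-9) { dx <- 1; dy <- 0; d <- 1 }
            push <- (config$min_separation_px - d) / 2
            x[i] <- min(max(x[i] - push * dx / d, lo_x), hi_x)
            y[i] <- min(max(y[i] - push * dy / d, lo_y), hi_y)
            x[j] <- min(max(x[j] + push * dx / d, lo_x), hi_x)
            y[j] <- min(max(y[j] + push * dy / d, lo_y), hi_y)
          }
        }
      }
    }
    boxes <- t(vapply(seq_len(n), function(i)
      .pig_box(x[i], y[i], len[i], wid[i], heading[i]), numeric(4)))
    rows[[f]] <- data.frame(frame = f, id = seq_len(n),
                            left = boxes[, 1], top = boxes[, 2],
                            width = boxes[, 3], height = boxes[, 4],
                            conf = 1, class = beh,
                            behavior = lv[beh])
  }
  gt <- do.call(rbind, rows)
  rownames(gt) <- NULL

  behavior_truth <- as.data.frame.matrix(
    table(factor(gt$id), factor(gt$behavior, levels = lv)))
  behavior_truth <- cbind(id = as.integer(rownames(behavior_truth)),
                          behavior_truth)
  rownames(behavior_truth) <- NULL

  detections <- degrade_detections(gt, config, reseed = FALSE)
  list(gt = gt, detections = detections, behavior_truth = behavior_truth,
       config = config)
}

#' Degrade a ground-truth table into a detection stream
#'
#' Applies only the corruption stage: Gaussian noise on box centre and size,
#' per-pig occlusion dropouts (geometric length), independent per-box
#' misses, Poisson false positives with uniform boxes, and the confidence
#' model. The counts actually injected are attached as attribute
#' `injected` (list with `n_missed`, `n_fp`), so metric fixtures know their
#' expected FP/FN exactly.
#'
#' @param gt ground-truth track table.
#' @param config a [scene_config()].
#' @param reseed set the RNG from `config$seed` first (`TRUE` for standalone
#'   use; [generate_scene()] passes `FALSE` to keep one stream).
#' @return detection table with columns `frame`, `id` (-1), box, `conf`,
#'   `class`, `behavior`.
#' @export
degrade_detections <- function(gt, config, reseed = TRUE) {
  if (reseed) set.seed(config$seed)
  lv <- behavior_levels()
  n_frames <- if (nrow(gt)) max(gt$frame) else 0L
  ids <- sort(unique(gt$id))

  # occlusion dropout state machine per pig
  occluded <- matrix(FALSE, length(ids), n_frames)
  if (config$occlusion_rate > 0 && n_frames > 0L) {
    stay <- 1 - 1 / config$occlusion_len
    for (i in seq_along(ids)) {
      state <- FALSE
      for (f in seq_len(n_frames)) {
        state <- if (state) stats::runif(1) < stay
                 else stats::runif(1) < config$occlusion_rate
        occluded[i, f] <- state
      }
    }
  }

  keep <- rep(TRUE, nrow(gt))
  if (nrow(gt)) {
    occ <- occluded[cbind(match(gt$id, ids), gt$frame)]
    miss <- stats::runif(nrow(gt)) < config$miss_rate
    keep <- !(occ | miss)
  }
  det <- gt[keep, , drop = FALSE]
  n_missed <- nrow(gt) - nrow(det)

  if (nrow(det)) {
    if (config$det_noise_px > 0) {
      det$left <- det$left + stats::rnorm(nrow(det), 0, config$det_noise_px)
      det$top <- det$top + stats::rnorm(nrow(det), 0, config$det_noise_px)
      det$width <- pmax(det$width +
        stats::rnorm(nrow(det), 0, config$det_noise_px), 5)
      det$height <- pmax(det$height +
        stats::rnorm(nrow(det), 0, config$det_noise_px), 5)
    }
    det$conf <- pmin(pmax(stats::rnorm(nrow(det), config$conf_true_mean,
                                       config$conf_true_sd), 0.01), 1)
    det$id <- -1L
  }

  fps_per_frame <- if (config$fp_rate > 0 && n_frames > 0L) {
    stats::rpois(n_frames, config$fp_rate)
  } else integer(n_frames)
  n_fp <- sum(fps_per_frame)
  if (n_fp > 0) {
    fpf <- rep(seq_len(n_frames), fps_per_frame)
    w <- stats::runif(n_fp, 50, 140)
    h <- stats::runif(n_fp, 35, 90)
    fp <- data.frame(frame = fpf, id = -1L,
                     left = stats::runif(n_fp, 0, config$pen_width - w),
                     top = stats::runif(n_fp, 0, config$pen_height - h),
                     width = w, height = h,
                     conf = pmin(pmax(stats::rnorm(n_fp, config$conf_false_mean,
                                                   config$conf_false_sd),
                                      0.01), 1),
                     class = sample.int(4L, n_fp, replace = TRUE))
    fp$behavior <- lv[fp$class]
    det <- rbind(det, fp)
  }
  det <- det[order(det$frame, -det$conf), , drop = FALSE]
  rownames(det) <- NULL
  attr(det, "injected") <- list(n_missed = n_missed, n_fp = n_fp)
  det
}

#' Deterministic detection surgery
#'
#' Complements the stochastic degrader with exact-count corruption for
#' metric fixtures: drop named (id, frame) ground-truth boxes and/or add
#' explicit false-positive boxes, with no randomness.
#'
#' @param gt ground-truth track table.
#' @param drop optional data.frame with columns `id`, `frame`: boxes to
#'   remove (e.g. frames 10-14 of one pig, creating an occlusion-gap
#'   fixture).
#' @param add_fp optional data.frame with columns `frame`, `left`, `top`,
#'   `width`, `height` and optionally `behavior`: boxes to inject.
#' @param conf confidence assigned to all surviving and injected boxes.
#' @return detection table; attribute `injected` carries the exact counts.
#' @export
inject_errors <- function(gt, drop = NULL, add_fp = NULL, conf = 1) {
  det <- gt
  n_missed <- 0L
  if (!is.null(drop) && nrow(drop)) {
    kill <- paste(det$id, det$frame) %in% paste(drop$id, drop$frame)
    n_missed <- sum(kill)
    det <- det[!kill, , drop = FALSE]
  }
  det$id <- -1L
  det$conf <- conf
  n_fp <- 0L
  if (!is.null(add_fp) && nrow(add_fp)) {
    n_fp <- nrow(add_fp)
    if (is.null(add_fp$behavior)) add_fp$behavior <- "other"
    fp <- data.frame(frame = as.integer(add_fp$frame), id = -1L,
                     left = add_fp$left, top = add_fp$top,
                     width = add_fp$width, height = add_fp$height,
                     conf = conf,
                     class = match(add_fp$behavior, behavior_levels()),
                     behavior = add_fp$behavior)
    det <- rbind(det, fp)
  }
  det <- det[order(det$frame, -det$conf), , drop = FALSE]
  rownames(det) <- NULL
  attr(det, "injected") <- list(n_missed = n_missed, n_fp = n_fp)
  det
}
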