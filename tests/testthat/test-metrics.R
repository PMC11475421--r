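test_that("per-frame matching handles the degenerate cases", {
  gt <- make_two_track_gt(5)
  m <- match_frames(gt, gt)
  expect_true(all(vapply(m, function(x) nrow(x$tp) == 2L, logical(1))))
  expect_true(all(vapply(m, function(x)
    length(x$fp_ids) + length(x$fn_ids) == 0L, logical(1))))

  m <- match_frames(gt, gt[0, ])
  expect_equal(sum(vapply(m, function(x) length(x$fn_ids), integer(1))),
               nrow(gt))
  expect_equal(sum(vapply(m, function(x) length(x$fp_ids), integer(1))), 0L)
})

test_that("frame matching agrees with exhaustive enumeration", {
  set.seed(55)
  for (k in 1:25) {
    n_gt <- sample(2:4, 1); n_pred <- sample(2:5, 1)
    gt <- data.frame(frame = 1L, id = seq_len(n_gt),
                     left = runif(n_gt, 0, 60), top = runif(n_gt, 0, 60),
                     width = runif(n_gt, 20, 50), height = runif(n_gt, 20, 50))
    pred <- data.frame(frame = 1L, id = seq_len(n_pred),
                       left = runif(n_pred, 0, 60), top = runif(n_pred, 0, 60),
                       width = runif(n_pred, 20, 50),
                       height = runif(n_pred, 20, 50))
    m <- match_frames(gt, pred, alpha = 0.3)[[1]]
    ious <- iou_matrix(as.matrix(gt[, 3:6]), as.matrix(pred[, 3:6]))
    best <- oracle_assignment(-ious, ious >= 0.3)
    expect_equal(nrow(m$tp), best$card)
    if (best$card > 0) {
      got <- sum(ious[cbind(match(m$tp$gt_id, gt$id),
                            match(m$tp$pred_id, pred$id))])
      expect_equal(got, -best$cost, tolerance = 1e-10)
    }
  }
})

test_that("MOTA arithmetic and identity-switch counting are exact", {
  # perfect tracking
  gt <- make_two_track_gt(10)
  expect_equal(mota_score(match_frames(gt, gt), gt)$mota, 1)

  # an all-miss tracker scores 1 - FN/gt = 0
  s <- mota_score(match_frames(gt[gt$frame <= 3, ], gt[0, ]),
                  gt[gt$frame <= 3, ])
  expect_equal(s$fn, 6L)
  expect_equal(s$mota, 0)

  # hand-built matchings: one switch for gt id 7 between its matched frames
  matchings <- list(
    list(frame = 1, tp = data.frame(gt_id = 7, pred_id = 1),
         fn_ids = integer(0), fp_ids = integer(0)),
    list(frame = 2, tp = data.frame(gt_id = 7, pred_id = 1)[0, ],
         fn_ids = 7L, fp_ids = integer(0)),
    list(frame = 3, tp = data.frame(gt_id = 7, pred_id = 2),
         fn_ids = integer(0), fp_ids = c(9L, 9L)))
  gt3 <- data.frame(frame = c(1, 2, 3), id = 7)
  s <- mota_score(matchings, gt3)
  expect_equal(s$ids, 1L)
  expect_equal(s$fp, 2L)
  expect_equal(s$fn, 1L)
  expect_equal(s$mota, 1 - (2 + 1 + 1) / 3)
})

test_that("IDF1 uses the optimal global bijection", {
  gt <- make_two_track_gt(10)
  expect_equal(idf1_score(gt, gt)$idf1, 1)

  # one gt track split in half: IDTP = 5, IDFP = IDFN = 5 -> IDF1 = 0.5
  gt1 <- gt[gt$id == 1, ]
  pred <- gt1
  pred$id <- ifelse(pred$frame <= 5, 1L, 2L)
  s <- idf1_score(gt1, pred)
  expect_equal(s$idtp, 5L)
  expect_equal(s$idf1, 0.5)
  expect_equal(s$idf1, oracle_idf1(gt1, pred))

  # random degradations against the exhaustive bijection oracle
  set.seed(66)
  for (k in 1:20) {
    gt_k <- make_two_track_gt(6)
    pred_k <- gt_k[runif(nrow(gt_k)) > 0.2, ]
    flip <- runif(nrow(pred_k)) < 0.3
    pred_k$id[flip] <- pred_k$id[flip] + 2L
    expect_equal(idf1_score(gt_k, pred_k)$idf1, oracle_idf1(gt_k, pred_k),
                 tolerance = 1e-12)
  }
})

test_that("HOTA matches hand computation on the midpoint id-flip fixture", {
  gt <- make_two_track_gt(10)
  perfect <- hota_score(gt, gt, alphas = 0.5)
  expect_equal(perfect$hota, 1)
  expect_equal(perfect$deta, 1)
  expect_equal(perfect$assa, 1)

  # detections perfect, but each id flips to a fresh one at the midpoint:
  # every A(c) = 5 / (10 + 5 - 5) = 0.5, DetA = 1, HOTA_alpha = sqrt(0.5)
  pred <- gt
  pred$id <- ifelse(pred$frame <= 5, pred$id, pred$id + 10L)
  h <- hota_score(gt, pred, alphas = 0.5)
  expect_equal(h$deta, 1)
  expect_equal(h$assa, 0.5)
  expect_equal(h$hota, sqrt(0.5))

  # algebraic identity on randomly degraded output
  set.seed(77)
  pred2 <- gt[runif(nrow(gt)) > 0.15, ]
  pred2$left <- pred2$left + rnorm(nrow(pred2), 0, 8)
  h2 <- hota_score(gt, pred2, alphas = 0.5)
  expect_equal(h2$hota^2, h2$deta * h2$assa, tolerance = 1e-12)
})

test_that("evaluate produces a coherent, order-invariant report", {
  gt <- make_two_track_gt(20)
  r <- evaluate_tracking(gt, gt)
  expect_equal(c(r$hota, r$mota, r$idf1), c(1, 1, 1))
  expect_equal(c(r$ids, r$fp, r$fn), c(0L, 0L, 0L))

  # construction-by-design degradation: exact FP/FN bookkeeping
  drop <- data.frame(id = c(1L, 1L, 2L), frame = c(3L, 4L, 10L))
  fps <- data.frame(frame = c(2L, 7L), left = 1000, top = 50, width = 80,
                    height = 50)
  det <- inject_errors(gt, drop = drop, add_fp = fps)
  pred <- det
  pred$id <- ifelse(pred$left < 500, 1L, ifelse(pred$left < 900, 2L, 3L))
  r <- evaluate_tracking(gt, pred)
  expect_equal(r$fn, 3L)
  expect_equal(r$fp, 2L)
  expect_equal(r$mota, 1 - 5 / nrow(gt))

  # shuffling prediction rows changes nothing
  set.seed(88)
  r2 <- evaluate_tracking(gt, pred[sample(nrow(pred)), ])
  expect_equal(r2[c("hota", "mota", "idf1", "ids", "fp", "fn")],
               r[c("hota", "mota", "idf1", "ids", "fp", "fn")])

  # MOTA decreases monotonically with injected false positives
  motas <- vapply(c(0, 3, 6, 9), function(k) {
    fp_k <- data.frame(frame = seq_len(max(1, k)), left = 1100, top = 600,
                       width = 60, height = 40)[seq_len(k), , drop = FALSE]
    p <- inject_errors(gt, add_fp = fp_k)
    p$id <- ifelse(p$left < 500, 1L, ifelse(p$left < 900, 2L, 3L))
    evaluate_tracking(gt, p)$mota
  }, numeric(1))
  expect_true(all(diff(motas) < 0))

  expect_warning(evaluate_tracking(gt, gt[gt$frame <= 10, ]),
                 "different frame ranges")
})

test_that("metrics reports serialise to flat JSON", {
  gt <- make_two_track_gt(5)
  r <- evaluate_tracking(gt, gt)
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics_report(r, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$hota, 1)
  expect_equal(back$ids, 0)
  expect_equal(back$iou_threshold, 0.5)
})
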