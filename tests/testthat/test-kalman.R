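model <- kf_model()

test_that("predict follows the unit-time constant-velocity model", {
  st <- list(mean = c(10, 20, 100, 1, 0, 0, 0), cov = diag(7))
  expect_equal(kf_predict(st, model)$mean[1:4], c(10, 20, 100, 1))

  st$mean <- c(10, 20, 100, 1, 2, -1, 5)
  expect_equal(kf_predict(st, model)$mean[1:4], c(12, 19, 105, 1))

  # covariance propagation against a dense hand-multiplied oracle
  set.seed(1)
  P <- diag(runif(7, 0.5, 4))
  st <- list(mean = c(10, 20, 100, 1, 2, -1, 5), cov = P)
  expected <- model$F %*% P %*% t(model$F) + model$Q
  expect_equal(kf_predict(st, model)$cov, (expected + t(expected)) / 2,
               tolerance = 1e-12)
})

test_that("predict guards against non-positive predicted area", {
  st <- list(mean = c(10, 20, 100, 1, 0, 0, -150), cov = diag(7))
  out <- kf_predict(st, model)
  expect_gt(out$mean[3], 0)
  expect_equal(out$mean[3], 100)  # s_dot reset to 0 before propagation
  expect_error(kf_predict(list(mean = rep(1, 7), cov = -diag(7)), model),
               "positive semi-definite")
})

test_that("update matches the scalar closed form and its limits", {
  z0 <- c(10, 20, 100, 1)
  st <- kf_init(z0)
  pri <- kf_predict(st, model)
  # zero innovation leaves the mean unchanged
  post <- kf_update(pri, pri$mean[1:4], model)
  expect_equal(post$mean, pri$mean, tolerance = 1e-12)

  # with diagonal P and R the update decouples: each observed component
  # must follow the scalar closed form x + p/(p+r) (z - x)
  P <- diag(c(4, 3, 50, 2, 1, 1, 1))
  st <- list(mean = c(10, 20, 100, 1, 0, 0, 0), cov = P)
  z <- c(13, 18, 130, 1.5)
  post <- kf_update(st, z, model)
  p <- diag(P)[1:4]; r <- diag(model$R)
  expect_equal(post$mean[1:4],
               st$mean[1:4] + p / (p + r) * (z - st$mean[1:4]),
               tolerance = 1e-9)
  expect_equal(diag(post$cov)[1:4], p - p^2 / (p + r), tolerance = 1e-9)

  # infinite observation noise: the posterior collapses onto the prior
  noisy <- kf_model(r_diag = c(1, 1, 10, 10) * 1e12)
  post <- kf_update(st, z, noisy)
  expect_lt(max(abs(post$mean - st$mean)), 1e-3)

  degenerate <- list(mean = st$mean, cov = matrix(0, 7, 7))
  broken <- kf_model(r_diag = c(1, 1, 1, 0))  # S has a zero row: singular
  expect_error(kf_update(degenerate, z, broken), "innovation")
})

test_that("virtual trajectories linearly interpolate the gap interior", {
  z1 <- c(0, 0, 100, 1); z2 <- c(10, 10, 200, 1)
  v <- make_virtual_trajectory(z1, z2, 0, 5)
  expect_length(v, 4L)
  expect_equal(v[[2]][1:2], c(4, 4))
  expect_equal(v[[2]][3], 140)

  expect_length(make_virtual_trajectory(z1, z2, 3, 4), 0L)
  expect_length(make_virtual_trajectory(z1, z2, 3, 3), 0L)

  one <- make_virtual_trajectory(z1, z2, 1, 3)
  expect_length(one, 1L)
  expect_equal(one[[1]], (z1 + z2) / 2, ignore_attr = TRUE)

  same <- make_virtual_trajectory(z1, z1, 0, 4)
  for (zz in same) expect_equal(zz, z1, ignore_attr = TRUE)
})

test_that("ORU re-update repairs the post-gap state", {
  # exact constant-velocity target; observations are noise-free
  z_at <- function(t) c(10 + 3 * t, 20 - 2 * t, 100, 1.5)
  st <- kf_init(z_at(0))
  for (t in 1:5) st <- kf_update(kf_predict(st, model), z_at(t), model)

  # an uninterrupted filter over frames 6..10
  cont <- st
  for (t in 6:10) cont <- kf_update(kf_predict(cont, model), z_at(t), model)

  # lost over 6..9, re-associated at 10, replayed along the exact virtual
  # trajectory (which coincides with the true track for linear motion)
  virtual <- make_virtual_trajectory(z_at(5), z_at(10), 5, 10)
  re <- kf_re_update(st, virtual, z_at(10), model)
  expect_lt(max(abs(re$mean - cont$mean)), 1e-6)

  # empty virtual sequence is exactly one predict + update
  expect_equal(kf_re_update(st, list(), z_at(6), model),
               kf_update(kf_predict(st, model), z_at(6), model),
               tolerance = 1e-12)

  # the re-updated posterior at t2 beats prediction alone across the gap
  set.seed(99)
  err_re <- err_pred <- numeric(20)
  for (k in 1:20) {
    stn <- kf_init(z_at(0) + rnorm(4, 0, c(1, 1, 5, 0.02)))
    for (t in 1:4) {
      stn <- kf_update(kf_predict(stn, model),
                       z_at(t) + rnorm(4, 0, c(1, 1, 5, 0.02)), model)
    }
    drift <- stn
    for (t in 5:9) drift <- kf_predict(drift, model)
    virtual <- make_virtual_trajectory(z_at(4), z_at(9), 4, 9)
    re <- kf_re_update(stn, virtual, z_at(9), model)
    truth <- z_at(9)[1:2]
    err_pred[k] <- sqrt(sum((drift$mean[1:2] - truth)^2))
    err_re[k] <- sqrt(sum((re$mean[1:2] - truth)^2))
  }
  expect_true(all(err_re <= err_pred))
})

test_that("covariance stays symmetric and r carries no velocity", {
  set.seed(3)
  st <- kf_init(c(100, 100, 5000, 1.6))
  for (step in 1:1000) {
    r_prior <- st$mean[4]
    st <- kf_predict(st, model)
    expect_identical(st$mean[4], r_prior)  # aspect ratio has no velocity
    if (runif(1) < 0.7) {
      z <- st$mean[1:4] + rnorm(4, 0, c(2, 2, 20, 0.05))
      z[3] <- max(z[3], 1); z[4] <- max(z[4], 0.05)
      st <- kf_update(st, z, model)
    }
    expect_lt(max(abs(st$cov - t(st$cov))), 1e-9)
  }
  # aspect-ratio rate is structurally absent from the transition model
  m <- kf_model()
  expect_equal(m$F[4, ], c(0, 0, 0, 1, 0, 0, 0))
})

test_that("innovations are white on a correctly specified simulation", {
  set.seed(2024)
  n <- 2000
  x <- c(300, 300, 6000, 1.5, 1, -0.5, 2)
  chol_q <- chol(model$Q); chol_r <- chol(model$R)
  st <- kf_init(x[1:4])
  norm_innov <- matrix(NA_real_, n, 4)
  for (t in 1:n) {
    x <- drop(model$F %*% x) + drop(t(chol_q) %*% rnorm(7))
    z <- x[1:4] + drop(t(chol_r) %*% rnorm(4))
    pri <- kf_predict(st, model)
    S <- model$H %*% pri$cov %*% t(model$H) + model$R
    innov <- z - drop(model$H %*% pri$mean)
    norm_innov[t, ] <- innov / sqrt(diag(S))
    st <- kf_update(pri, z, model)
  }
  v <- apply(norm_innov[-(1:50), ], 2, stats::var)  # drop the burn-in
  expect_true(all(v > 0.8 & v < 1.2))
})
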