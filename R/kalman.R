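# Constant-velocity Kalman filter on the 7-D box state
# x = (u, v, s, r, u_dot, v_dot, s_dot): box centre, area, aspect ratio and
# the per-frame rates of the first three. The aspect ratio carries no
# velocity: the motion model holds it constant. Time step is one frame.

#' Motion and noise model for the box-state Kalman filter
#'
#' Builds the constant-velocity state-transition matrix `F`, process noise
#' `Q`, observation matrix `H` (extracting `(u, v, s, r)`) and observation
#' noise `R`. Defaults follow the SORT-family convention: unit observation
#' noise on the centre coordinates with a 10x weight on area and aspect
#' ratio, and a small process noise on the rate states. None of these values
#' is dictated by the tracking contracts; they are tuning knobs exposed
#' through [tracker_config()].
#'
#' @param r_diag length-4 diagonal of the observation-noise covariance on
#'   `(u, v, s, r)`.
#' @param q_diag length-7 diagonal of the process-noise covariance.
#' @return list with elements `F`, `Q`, `H`, `R`.
#' @export
kf_model <- function(r_diag = c(1, 1, 10, 10),
                     q_diag = c(1, 1, 1, 0.01, 0.01, 0.01, 1e-4)) {
  F <- diag(7)
  F[1, 5] <- F[2, 6] <- F[3, 7] <- 1
  H <- cbind(diag(4), matrix(0, 4, 3))
  list(F = F, Q = diag(q_diag), H = H, R = diag(r_diag))
}

#' Initialise filter state from a first observation
#'
#' Velocities start at zero with large uncertainty (velocities are
#' unobserved at birth: their initial variance is set well above the
#' position variance so the first updates dominate the prior).
#'
#' @param z observation `(u, v, s, r)` from [box_to_obs()].
#' @param p_pos initial variance on the observed components.
#' @param p_vel initial variance on the rate components.
#' @return Kalman state: list with `mean` (length 7) and `cov` (7x7).
#' @export
kf_init <- function(z, p_pos = 10, p_vel = 1e4) {
  list(mean = c(unname(z), 0, 0, 0),
       cov = diag(c(rep(p_pos, 4), rep(p_vel, 3))))
}

.check_psd <- function(P, tol = 1e-8, what = "covariance") {
  if (max(abs(P - t(P))) > 1e-6) {
    stop(what, " matrix is not symmetric", call. = FALSE)
  }
  ev <- eigen((P + t(P)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    stop(what, " matrix is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Kalman predict step
#'
#' Propagates the state one frame: `mean' = F mean`, `P' = F P F^T + Q`.
#' If the current area rate would drive the predicted area non-positive
#' (`s + s_dot <= 0`), the rate is reset to zero before propagation so the
#' predicted box stays valid through long occlusions.
#'
#' @param state Kalman state (`mean`, `cov`).
#' @param model from [kf_model()].
#' @return predicted (prior) Kalman state.
#' @export
kf_predict <- function(state, model) {
  .check_psd(state$cov)
  mean <- state$mean
  if (mean[3] + mean[7] <= 0) mean[7] <- 0
  P <- model$F %*% state$cov %*% t(model$F) + model$Q
  list(mean = drop(model$F %*% mean), cov = (P + t(P)) / 2)
}

#' Kalman update step
#'
#' Standard linear update: gain `K = P H^T (H P H^T + R)^{-1}`, posterior
#' mean `x + K (z - H x)` and covariance `(I - K H) P` (symmetrised).
#'
#' @param state predicted (prior) Kalman state.
#' @param z observation `(u, v, s, r)`.
#' @param model from [kf_model()].
#' @return posterior Kalman state.
#' @export
kf_update <- function(state, z, model) {
  H <- model$H
  P <- state$cov
  S <- H %*% P %*% t(H) + model$R
  sv <- svd(S, nu = 0, nv = 0)$d
  kap <- if (min(sv) > 0) max(sv) / min(sv) else Inf
  if (!is.finite(kap) || kap > 1e12) {
    stop("singular innovation covariance (condition number ", format(kap), ")",
         call. = FALSE)
  }
  K <- P %*% t(H) %*% solve(S)
  innov <- unname(z) - drop(H %*% state$mean)
  mean <- state$mean + drop(K %*% innov)
  P2 <- (diag(7) - K %*% H) %*% P
  list(mean = mean, cov = (P2 + t(P2)) / 2)
}

#' Virtual trajectory across an occlusion gap
#'
#' Linear interpolation between the last observation before the track was
#' lost (`z_t1` at frame `t1`) and the observation that re-associated it
#' (`z_t2` at frame `t2`), evaluated at every interior frame `t1 < t < t2`.
#' Each of `(u, v, s, r)` is interpolated componentwise at fraction
#' `(t - t1) / (t2 - t1)`.
#'
#' @param z_t1,z_t2 observations `(u, v, s, r)`.
#' @param t1,t2 frame indices, `t2 > t1`.
#' @return list of `t2 - t1 - 1` observations (empty when `t2 <= t1 + 1`).
#' @export
make_virtual_trajectory <- function(z_t1, z_t2, t1, t2) {
  if (t2 <= t1 + 1) return(list())
  lapply(seq(t1 + 1, t2 - 1), function(t) {
    a <- (t - t1) / (t2 - t1)
    unname(z_t1) * (1 - a) + unname(z_t2) * a
  })
}

#' Re-update along a virtual trajectory (ORU)
#'
#' Repairs the filter after an occlusion gap: starting from the posterior at
#' the last real observation, the filter is replayed with a predict/update
#' pass for each virtual observation in order and finally for the real
#' re-associating observation. With an empty virtual sequence this is a
#' plain predict + update with `z_t2`.
#'
#' @param state_at_t1 posterior Kalman state at the last real observation.
#' @param virtual list of interior observations from
#'   [make_virtual_trajectory()].
#' @param z_t2 the re-associating real observation.
#' @param model from [kf_model()].
#' @return posterior Kalman state at the re-association frame.
#' @export
kf_re_update <- function(state_at_t1, virtual, z_t2, model) {
  state <- state_at_t1
  for (zbar in virtual) {
    state <- kf_update(kf_predict(state, model), zbar, model)
  }
  kf_update(kf_predict(state, model), z_t2, model)
}

# Predicted box (corner format) from a prior state, for association.
kf_predicted_box <- function(state) {
  z <- state$mean[1:4]
  if (z[3] <= 0) z[3] <- .Machine$double.eps
  if (z[4] <= 0) z[4] <- .Machine$double.eps
  obs_to_box(z)
}
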