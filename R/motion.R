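#' Constant-velocity Kalman filter over box state
#'
#' The motion state is an 8-vector `(cx, cy, a, h, vcx, vcy, va, vh)`:
#' box centre, aspect ratio, height and their per-frame velocities, with
#' an 8x8 covariance.  Process and observation noise are parameterised
#' relative to the box height, the convention of the original Deep SORT
#' motion model: position/size standard deviations scale with
#' `weight_position * h` and velocity standard deviations with
#' `weight_velocity * h`.  The frame interval is fixed at dt = 1.
#'
#' @name motion_model
NULL

KF_NDIM <- 4L

kf_transition <- function() {
  F_ <- diag(8)
  F_[cbind(1:4, 5:8)] <- 1
  F_
}

new_kf_state <- function(mean, cov, wp, wv) {
  structure(list(mean = as.numeric(mean), cov = cov,
                 weight_position = wp, weight_velocity = wv),
            class = "kf_state")
}

#' @export
print.kf_state <- function(x, ...) {
  cat("<kf_state> mean:", format(round(x$mean, 3)), "\n")
  invisible(x)
}

#' Initialise a motion state from a measurement
#'
#' The state mean is the measurement with zero velocities; the initial
#' covariance diagonal is built from height-proportional standard
#' deviations (twice the positional weight for position/size terms, ten
#' times the velocity weight for velocity terms, with small constants
#' for the dimensionless aspect ratio).
#'
#' @param z measurement in xyah form `c(cx, cy, a, h)`.
#' @param weight_position position-noise scale relative to box height
#'   (default 1/20).
#' @param weight_velocity velocity-noise scale relative to box height
#'   (default 1/160).
#' @return A `kf_state` (list with `mean`, `cov`).
#' @export
kf_initiate <- function(z, weight_position = 1 / 20, weight_velocity = 1 / 160) {
  z <- as.numeric(z)
  if (length(z) != 4L || !all(is.finite(z))) stop("measurement must be finite xyah")
  if (z[3L] <= 0 || z[4L] <= 0) stop("aspect and height must be positive")
  h <- z[4L]
  std <- c(2 * weight_position * h, 2 * weight_position * h, 1e-2,
           2 * weight_position * h,
           10 * weight_velocity * h, 10 * weight_velocity * h, 1e-5,
           10 * weight_velocity * h)
  new_kf_state(c(z, 0, 0, 0, 0), diag(std^2), weight_position, weight_velocity)
}

#' Predict one frame ahead
#'
#' Applies the dt = 1 constant-velocity transition and inflates the
#' covariance with height-proportional process noise.
#'
#' @param s a `kf_state`.
#' @return The predicted `kf_state`.
#' @export
kf_predict <- function(s) {
  h <- s$mean[4L]
  wp <- s$weight_position; wv <- s$weight_velocity
  std <- c(wp * h, wp * h, 1e-2, wp * h, wv * h, wv * h, 1e-5, wv * h)
  F_ <- kf_transition()
  mean <- as.numeric(F_ %*% s$mean)
  cov <- F_ %*% s$cov %*% t(F_) + diag(std^2)
  cov <- (cov + t(cov)) / 2
  new_kf_state(mean, cov, wp, wv)
}

# Project state into measurement space: returns list(mean4, S).
kf_project <- function(s) {
  h <- s$mean[4L]
  wp <- s$weight_position
  std <- c(wp * h, wp * h, 1e-1, wp * h)
  S <- s$cov[1:4, 1:4] + diag(std^2)
  list(mean = s$mean[1:4], S = (S + t(S)) / 2)
}

#' Kalman measurement update
#'
#' Standard correction with the measurement matrix selecting
#' `(cx, cy, a, h)`.
#'
#' @param s a `kf_state`.
#' @param z measurement in xyah form.
#' @return The posterior `kf_state`.
#' @export
kf_update <- function(s, z) {
  z <- as.numeric(z)
  if (length(z) != 4L || !all(is.finite(z))) stop("measurement must be finite xyah")
  pr <- kf_project(s)
  K <- tryCatch(t(solve(pr$S, t(s$cov[, 1:4, drop = FALSE]))),
                error = function(e) stop("innovation covariance is singular"))
  innov <- z - pr$mean
  mean <- s$mean + as.numeric(K %*% innov)
  cov <- s$cov - K %*% pr$S %*% t(K)
  cov <- (cov + t(cov)) / 2
  new_kf_state(mean, cov, s$weight_position, s$weight_velocity)
}

#' Squared Mahalanobis gating distances
#'
#' Distance of each measurement from the state's projected measurement
#' distribution, used as a hard gate during cascade matching (the
#' conventional threshold is the 0.95 chi-square quantile with 4
#' degrees of freedom, 9.4877).
#'
#' @param s a `kf_state`.
#' @param zs measurements in xyah form, one per row (or a single vector).
#' @return Numeric vector of squared Mahalanobis distances, all >= 0.
#' @export
kf_gating_distance <- function(s, zs) {
  if (is.null(dim(zs))) zs <- matrix(zs, nrow = 1L)
  zs <- as.matrix(zs)
  if (ncol(zs) != 4L) stop("measurements must have 4 columns")
  pr <- kf_project(s)
  d <- sweep(zs, 2L, pr$mean)
  L <- tryCatch(chol(pr$S),
                error = function(e) stop("innovation covariance is singular"))
  y <- backsolve(L, t(d), transpose = TRUE)
  colSums(y^2)
}

#' Chi-square gating threshold
#'
#' @param p quantile (default 0.95).
#' @param df degrees of freedom (default 4, the measurement dimension).
#' @return The squared-distance threshold.
#' @export
chi2_gate <- function(p = 0.95, df = 4) stats::qchisq(p, df)
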