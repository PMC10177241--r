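#' Triaxial accelerometer trace
#'
#' Container for a local-frame accelerometer recording with fused Euler
#' angles, as produced by waist-mounted consumer IMUs: per-sample local
#' specific force (m/s^2) on three axes plus roll/pitch/yaw (rad) at a
#' uniform sampling rate.
#'
#' @param time time grid, s (uniform within 1 ppm).
#' @param acceleration n x 3 matrix of local-frame specific force, m/s^2
#'   (columns x, y, z).
#' @param euler n x 3 matrix of roll, pitch, yaw, rad.
#' @param sample_rate sampling rate, Hz.
#' @return An object of class `imu_trace`.
#' @export
imu_trace <- function(time, acceleration, euler, sample_rate) {
  acceleration <- as.matrix(acceleration)
  euler <- as.matrix(euler)
  n <- length(time)
  stopifnot(n >= 2, nrow(acceleration) == n, nrow(euler) == n,
            ncol(acceleration) == 3, ncol(euler) == 3,
            is.numeric(sample_rate), sample_rate > 0)
  .check_uniform(time)
  colnames(acceleration) <- c("x", "y", "z")
  colnames(euler) <- c("roll", "pitch", "yaw")
  structure(list(time = as.numeric(time), acceleration = acceleration,
                 euler = euler, sample_rate = sample_rate),
            class = "imu_trace")
}

#' @exportS3Method base::print
print.imu_trace <- function(x, ...) {
  cat(sprintf("<imu_trace> %d samples @ %g Hz (%.2f s)\n",
              length(x$time), x$sample_rate, max(x$time) - min(x$time)))
  invisible(x)
}

# uniform-grid check (relative step spread below tol)
.check_uniform <- function(time, tol = 1e-6) {
  dt <- diff(time)
  if (any(!is.finite(dt)) || any(dt <= 0) ||
      (max(dt) - min(dt)) > tol * mean(dt)) {
    stop("non-uniform time grid: resample required before integration")
  }
  invisible(mean(dt))
}

#' Rotate a local-frame trace into global, gravity-free acceleration
#'
#' For every sample, `a_global = R(roll, pitch, yaw) %*% a_local +
#' c(0, 0, -9.81)` with `R` the intrinsic Z-Y-X (yaw-pitch-roll) rotation of
#' [euler_to_matrix()]. The gravity term removes the accelerometer's
#' gravity reaction, so the output is the inertial acceleration of the COM
#' in the global frame; a stationary sensor maps to zero on all axes.
#'
#' @param trace an [imu_trace()].
#' @return n x 3 matrix of global acceleration, m/s^2 (columns x, y, z).
#' @export
#' @examples
#' # stationary sensor: local z channel carries +9.81, global is zero
#' tm <- seq(0, 1, by = 0.01)
#' acc <- cbind(0, 0, rep(9.81, length(tm)))
#' tr <- imu_trace(tm, acc, matrix(0, length(tm), 3), 100)
#' max(abs(to_global_frame(tr)))
to_global_frame <- function(trace) {
  stopifnot(inherits(trace, "imu_trace"))
  ang <- trace$euler
  if (any(!is.finite(ang))) {
    stop(sprintf("non-finite Euler angles at sample %d",
                 which(!is.finite(rowSums(ang)))[1]))
  }
  a <- trace$acceleration
  cr <- cos(ang[, 1]); sr <- sin(ang[, 1])
  cp <- cos(ang[, 2]); sp <- sin(ang[, 2])
  cy <- cos(ang[, 3]); sy <- sin(ang[, 3])
  # rows of R = Rz(yaw) Ry(pitch) Rx(roll), applied vectorized
  gx <- cy * cp * a[, 1] + (cy * sp * sr - sy * cr) * a[, 2] +
    (cy * sp * cr + sy * sr) * a[, 3]
  gy <- sy * cp * a[, 1] + (sy * sp * sr + cy * cr) * a[, 2] +
    (sy * sp * cr - cy * sr) * a[, 3]
  gz <- -sp * a[, 1] + cp * sr * a[, 2] + cp * cr * a[, 3] - G_ACCEL
  cbind(x = gx, y = gy, z = gz)
}

#' Remove the linear trend from each acceleration axis
#'
#' Fits and subtracts a least-squares straight line per axis over the
#' analysis window, removing residual low-frequency bias (sensor offset and
#' slow orientation error) before integration. Output columns have zero
#' mean and zero linear slope to numerical tolerance; constant input maps
#' to zeros.
#'
#' @param acceleration n x 3 matrix (or a vector for a single axis).
#' @param time optional time grid; defaults to sample index.
#' @return Detrended matrix (or vector) of the same shape.
#' @export
detrend_acceleration <- function(acceleration, time = NULL) {
  vec <- is.null(dim(acceleration))
  a <- if (vec) matrix(acceleration, ncol = 1) else as.matrix(acceleration)
  n <- nrow(a)
  if (n < 2) stop("detrending needs at least 2 samples")
  t <- if (is.null(time)) seq_len(n) else as.numeric(time)
  X <- cbind(1, t)
  fit <- stats::lm.fit(X, a)
  out <- a - X %*% fit$coefficients
  if (vec) drop(out) else out
}

#' Head-point track digitized from video
#'
#' A calibrated image-plane track of a fixed head point, used for the
#' fore-aft integration constant and for traverse speed.
#'
#' @param x_m fore-aft positions, m (calibrated).
#' @param z_m vertical positions, m; defaults to zeros.
#' @param frame_rate video frame rate, Hz (default 120).
#' @param frame_index frame numbers; defaults to `0:(n-1)`.
#' @return An object of class `point_track` (a data.frame with attribute
#'   `frame_rate`).
#' @export
point_track <- function(x_m, z_m = rep(0, length(x_m)), frame_rate = 120,
                        frame_index = seq_along(x_m) - 1L) {
  stopifnot(length(x_m) >= 2, frame_rate > 0,
            length(z_m) == length(x_m), length(frame_index) == length(x_m))
  structure(data.frame(frame_index = frame_index, x_m = x_m, z_m = z_m),
            frame_rate = frame_rate, class = c("point_track", "data.frame"))
}

#' Fore-aft speed at touchdown from a pre-touchdown head track
#'
#' Least-squares slope of the fore-aft head position against time over the
#' last `n_frames` frames before the initial touchdown: the integration
#' constant for the fore-aft velocity integral.
#'
#' @param track a [point_track()].
#' @param n_frames number of trailing frames to use (default 10).
#' @return Fore-aft speed, m/s.
#' @export
#' @examples
#' trk <- point_track(0.005 * (0:9), frame_rate = 120)
#' estimate_initial_velocity(trk)  # 0.6 m/s
estimate_initial_velocity <- function(track, n_frames = 10) {
  stopifnot(inherits(track, "point_track"))
  n <- nrow(track)
  if (n < 2 || n_frames < 2) {
    stop("insufficient data: need at least 2 frames to fit a velocity")
  }
  use <- track[max(1, n - n_frames + 1):n, ]
  fr <- attr(track, "frame_rate")
  t <- use$frame_index / fr
  unname(coef(lm(use$x_m ~ t))[2])
}

#' Doubly integrate global acceleration to COM velocity and position
#'
#' Cumulative trapezoidal integration on a uniform grid: once to velocity,
#' seeded with per-axis integration constants, and again to position,
#' seeded at the origin. Axes whose initial velocity is `NA` are closed by
#' the steady-state assumption selected in `closure`:
#' `"zero_mean"` (default) shifts the velocity so its mean over the window
#' is zero — appropriate for the mediolateral and vertical axes of a
#' steady-state stride, whose net displacement per cycle is zero — while
#' `"zero_start"` simply seeds them at rest.
#'
#' @param acceleration n x 3 matrix of global acceleration, m/s^2.
#' @param initial_velocity length-3 numeric; `NA` entries are closed per
#'   `closure`. Typically `c(v0_foreaft, NA, NA)` with the fore-aft
#'   constant from [estimate_initial_velocity()].
#' @param sample_rate sampling rate, Hz (ignored if `time` is given).
#' @param time optional explicit time grid; must be uniform.
#' @param closure closure rule for `NA` initial velocities.
#' @return An object of class `global_kinematics`: list with `time`,
#'   `acceleration`, `velocity`, `position` (n x 3), `initial_velocity`,
#'   `sample_rate`.
#' @export
#' @examples
#' a <- matrix(0, 101, 3); a[, 1] <- 1    # 1 m/s^2 fore-aft from rest
#' k <- integrate_kinematics(a, c(0, 0, 0), sample_rate = 100)
#' k$velocity[101, 1]; k$position[101, 1] # 1.0 m/s, 0.5 m
integrate_kinematics <- function(acceleration,
                                 initial_velocity = c(NA, NA, NA),
                                 sample_rate = NULL, time = NULL,
                                 closure = c("zero_mean", "zero_start")) {
  closure <- match.arg(closure)
  a <- as.matrix(acceleration)
  stopifnot(ncol(a) == 3, nrow(a) >= 2, length(initial_velocity) == 3)
  if (is.null(time)) {
    stopifnot(!is.null(sample_rate), sample_rate > 0)
    time <- (seq_len(nrow(a)) - 1) / sample_rate
  } else {
    .check_uniform(time)
    if (is.null(sample_rate)) sample_rate <- 1 / mean(diff(time))
  }
  v <- pracma::cumtrapz(time, a)
  v0 <- initial_velocity
  for (j in 1:3) {
    if (is.na(v0[j])) {
      v0[j] <- if (closure == "zero_mean") -mean(v[, j]) else 0
    }
    v[, j] <- v[, j] + v0[j]
  }
  p <- pracma::cumtrapz(time, v)
  colnames(v) <- colnames(p) <- c("x", "y", "z")
  structure(list(time = time, acceleration = a, velocity = v, position = p,
                 initial_velocity = setNames(v0, c("x", "y", "z")),
                 sample_rate = sample_rate),
            class = "global_kinematics")
}

#' @exportS3Method base::print
print.global_kinematics <- function(x, ...) {
  cat(sprintf("<global_kinematics> %d samples @ %g Hz, v0 = (%.3f, %.3f, %.3f) m/s\n",
              length(x$time), x$sample_rate,
              x$initial_velocity[1], x$initial_velocity[2],
              x$initial_velocity[3]))
  invisible(x)
}

#' Reconstruct per-stride COM kinematics from an IMU trace
#'
#' Runs the full single-trial processing chain: rotate the local trace to
#' gravity-free global acceleration, cut it into closed-open
#' `[touchdown, next touchdown)` stride windows, optionally detrend each
#' window per axis, and doubly integrate with the fore-aft integration
#' constant supplied per stride (mediolateral and vertical axes use the
#' zero-mean velocity closure).
#'
#' Detrending is off by default: over a window of only one or two pendular
#' cycles a straight-line fit removes genuine periodic signal (the
#' least-squares slope of a sine-phase cycle is nonzero), which corrupts
#' the double integral. Enable it for recordings with slow sensor-bias
#' drift, where the removed line is dominated by the drift.
#'
#' @param trace an [imu_trace()].
#' @param stride_events data.frame with `touchdown_s` and
#'   `next_touchdown_s` columns (rows with `NA` next touchdown are ignored).
#' @param v0_foreaft numeric vector (recycled) of fore-aft touchdown speeds,
#'   m/s, one per stride.
#' @param detrend logical: apply [detrend_acceleration()] per window
#'   (default `FALSE`).
#' @return A list of `global_kinematics`, one per complete stride.
#' @export
process_trial <- function(trace, stride_events, v0_foreaft,
                          detrend = FALSE) {
  stopifnot(inherits(trace, "imu_trace"))
  ev <- stride_events[!is.na(stride_events$next_touchdown_s), , drop = FALSE]
  if (nrow(ev) == 0) stop("no complete strides in events table")
  v0_foreaft <- rep_len(v0_foreaft, nrow(ev))
  a_g <- to_global_frame(trace)
  out <- vector("list", nrow(ev))
  # trim half a sample at each end: every retained sample's averaging
  # window then lies inside the stride, clear of the bounding exchanges
  half <- 0.5 / trace$sample_rate
  for (i in seq_len(nrow(ev))) {
    idx <- which(trace$time >= ev$touchdown_s[i] + half - 1e-9 &
                   trace$time < ev$next_touchdown_s[i] - half - 1e-9)
    if (length(idx) < 3) stop(sprintf("stride %d window too short", i))
    a_w <- a_g[idx, , drop = FALSE]
    if (detrend) a_w <- detrend_acceleration(a_w, trace$time[idx])
    out[[i]] <- integrate_kinematics(
      a_w, initial_velocity = c(v0_foreaft[i], NA, NA),
      time = trace$time[idx])
  }
  out
}
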