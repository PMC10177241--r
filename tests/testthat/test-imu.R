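make_trace <- function(a_local, euler, sr = 100) {
  n <- nrow(a_local)
  imu_trace((seq_len(n) - 1) / sr, a_local, euler, sr)
}

test_that("rotation removes gravity for stationary orientations", {
  n <- 20
  # flat mounting: local z carries +g
  tr <- make_trace(cbind(0, 0, rep(9.81, n)), matrix(0, n, 3))
  expect_equal(max(abs(to_global_frame(tr))), 0, tolerance = 1e-12)
  # 90-degree pitch: gravity reaction on the local fore-aft axis
  eul <- cbind(0, rep(pi / 2, n), 0)
  tr2 <- make_trace(cbind(rep(-9.81, n), 0, 0), eul)
  expect_equal(max(abs(to_global_frame(tr2))), 0, tolerance = 1e-9)
})

test_that("the Euler rotation preserves vector norms", {
  set.seed(5)
  for (i in 1:25) {
    ang <- runif(3, -pi, pi)
    v <- rnorm(3)
    R <- euler_to_matrix(ang[1], ang[2], ang[3])
    expect_equal(sqrt(sum((R %*% v)^2)), sqrt(sum(v^2)), tolerance = 1e-12)
  }
})

test_that("non-finite Euler angles are reported with the sample index", {
  eul <- matrix(0, 10, 3); eul[4, 2] <- NaN
  tr <- make_trace(matrix(0, 10, 3), matrix(0, 10, 3))
  tr$euler <- eul
  expect_error(to_global_frame(tr), "sample 4")
})

test_that("linear detrend removes ramps and leaves full-period cosines intact", {
  t <- seq(0, 1, by = 0.005)
  expect_equal(detrend_acceleration(3 * t + 1, t), rep(0, length(t)),
               tolerance = 1e-10)
  # cosine over integer periods is orthogonal to both basis functions
  s <- cos(2 * pi * 3 * t)
  expect_equal(detrend_acceleration(s, t), s, tolerance = 1e-2)
  # sinusoid + ramp: the ramp fitted by an independent lm() is removed
  y <- s + 2.5 * t - 0.7
  fit <- lm(y ~ t)
  expect_equal(detrend_acceleration(y, t), unname(y - fitted(fit)),
               tolerance = 1e-12)
  expect_error(detrend_acceleration(1), "at least 2")
})

test_that("initial fore-aft velocity is the slope of the pre-touchdown track", {
  trk <- point_track(0.005 * (0:9), frame_rate = 120)
  expect_equal(estimate_initial_velocity(trk), 0.6, tolerance = 1e-12)
  expect_equal(estimate_initial_velocity(point_track(rep(0.3, 10))), 0)
  # noisy constant-velocity track: matches an independent lm() fit exactly
  set.seed(8)
  x <- 0.6 * (0:11) / 120 + rnorm(12, sd = 1e-3)
  trk_n <- point_track(x, frame_rate = 120)
  tt <- (2:11) / 120
  fit <- lm(x[3:12] ~ tt)
  expect_equal(estimate_initial_velocity(trk_n, n_frames = 10),
               unname(coef(fit)[2]), tolerance = 1e-12)
  expect_lt(abs(estimate_initial_velocity(trk_n) - 0.6), 0.05)
})

test_that("double integration reproduces closed-form kinematics", {
  n <- 101; sr <- 100
  a <- matrix(0, n, 3); a[, 1] <- 1
  k <- integrate_kinematics(a, c(0, 0, 0), sample_rate = sr)
  expect_equal(unname(k$velocity[n, 1]), 1.0, tolerance = 1e-12)
  expect_equal(unname(k$position[n, 1]), 0.5, tolerance = 1e-6)

  k0 <- integrate_kinematics(matrix(0, n, 3), c(0.6, 0, 0), sample_rate = sr)
  expect_equal(unname(k0$position[, 1]), 0.6 * (0:100) / sr,
               tolerance = 1e-12)

  # a(t) = -A w^2 sin(wt), v0 = A w  ->  x(t) = A sin(wt)
  A <- 0.2; w <- 2 * pi
  t <- (0:200) / 100
  a_s <- cbind(-A * w^2 * sin(w * t), 0, 0)
  ks <- integrate_kinematics(a_s, c(A * w, 0, 0), time = t)
  expect_lt(max(abs(ks$position[, 1] - A * sin(w * t))), 1e-3)
})

test_that("zero-mean closure recovers axes with zero net displacement", {
  A <- 0.1; w <- 2 * pi; t <- (0:400) / 100
  a <- cbind(0, -A * w^2 * sin(w * t), 0)
  k <- integrate_kinematics(a, c(0, NA, NA), time = t)
  expect_lt(max(abs(k$velocity[, 2] - A * w * cos(w * t))), 5e-3)
  expect_lt(abs(k$initial_velocity[["y"]] - A * w), 5e-3)
})

test_that("a non-uniform grid is rejected with a resample message", {
  t_bad <- c(0, 0.01, 0.02, 0.05, 0.06)
  a <- matrix(0, 5, 3)
  expect_error(integrate_kinematics(a, c(0, 0, 0), time = t_bad), "resample")
})

test_that("differentiate after integrate returns the input acceleration", {
  set.seed(2)
  t <- (0:300) / 100
  # smooth random band-limited signal
  a1 <- rowSums(sapply(1:4, function(k) rnorm(1) * sin(2 * pi * k * t / 3)))
  a <- cbind(a1, 0.5 * a1, -a1)
  k <- integrate_kinematics(a, c(0, 0, 0), time = t)
  v <- k$velocity
  dv <- apply(v, 2, function(col) diff(col) / diff(t))
  mid <- (a[-1, ] + a[-nrow(a), ]) / 2   # trapezoid midpoint convention
  expect_lt(max(abs(dv - mid)), 1e-9)
})

test_that("sensor trace rotated back matches the truth acceleration", {
  cfg <- sim_config(L = 1.2, ml_sway_amplitude = 0.08, n_strides = 2,
                    orientation = c(0.1, -0.2, 0.4))
  truth <- simulate_pendulum_trial(cfg)
  imu <- sensor_model(truth, sampling = "instantaneous")
  expect_lt(max(abs(to_global_frame(imu) - truth$acceleration)), 1e-9)
  # averaged sampling differs only at the O(h^2) smoothing level away from
  # exchanges, and stays bounded at the exchange samples
  imu_avg <- sensor_model(truth)
  err <- abs(to_global_frame(imu_avg) - truth$acceleration)
  expect_lt(sqrt(mean(err^2)), 0.05)
})

test_that("vendor-dialect traces round-trip through the text format", {
  cfg <- sim_config(L = 1, n_strides = 1, noise_sd = 0.05, seed = 21)
  truth <- simulate_pendulum_trial(cfg)
  imu <- sensor_model(truth)
  path <- withr::local_tempfile(fileext = ".csv")
  write_imu_trace(imu, path, seed = 21)
  back <- read_imu_trace(path)
  expect_equal(back$acceleration, imu$acceleration, tolerance = 1e-12)
  expect_equal(back$sample_rate, imu$sample_rate, tolerance = 1e-6)

  # vendor column names resolved through a column map
  df <- read.csv(path, comment.char = "#")
  names(df) <- c("T", "AccX", "AccY", "AccZ", "Roll", "Pitch", "Yaw")
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path2, row.names = FALSE)
  cmap <- c(time_s = "T", ax = "AccX", ay = "AccY", az = "AccZ",
            roll_rad = "Roll", pitch_rad = "Pitch", yaw_rad = "Yaw")
  back2 <- read_imu_trace(path2, column_map = cmap)
  expect_equal(back2$acceleration, imu$acceleration, tolerance = 1e-12)
})
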