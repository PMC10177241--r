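#' Configuration for a simulated brachiation trial
#'
#' Bundles the physical and sensor parameters of one continuous-contact
#' brachiation trial. The centre of mass (COM) is modelled as a point mass on
#' a massless arm of length `L` swinging below a pivot (the gripping hand);
#' at each handhold exchange the pivot advances by one inter-bar distance,
#' the pendulum angle flips sign and an angular-velocity `drive_impulse`
#' (muscular boost) is added. Mediolateral sway is a kinematic sinusoid at
#' stride frequency superimposed on the planar pendulum.
#'
#' @param L pendulum length, m: vertical distance from the substrate contact
#'   point (fingertips) to the COM. Must be positive.
#' @param mass body mass, kg.
#' @param amplitude0 initial swing angle, rad, in (0, pi/2); `NULL` (default)
#'   uses the geometry-matched amplitude `asin(d/(2L))` for inter-bar
#'   distance `d`, which makes handhold exchanges position-continuous.
#'   `0` is accepted and yields a motionless hang.
#' @param damping viscous damping coefficient, 1/s (>= 0).
#' @param drive_impulse angular-velocity boost applied at each handhold
#'   exchange, rad/s (>= 0).
#' @param ml_sway_amplitude mediolateral sway amplitude, m.
#' @param ml_sway_phase mediolateral sway phase, rad.
#' @param n_strides number of complete reference-limb strides to simulate
#'   (a stride spans two handhold exchanges).
#' @param inter_bar_distance rung spacing of the runway, m (default 0.135).
#' @param sample_rate output sampling rate, Hz (default 100).
#' @param noise_sd additive sensor noise standard deviation, m/s^2 (used by
#'   [sensor_model()]).
#' @param orientation sensor mounting orientation, Euler angles
#'   (roll, pitch, yaw) in rad (used by [sensor_model()]).
#' @param orientation_drift slow linear drift rate of the mounting angles,
#'   rad/s (used by [sensor_model()]).
#' @param duty_factor contact fraction of the stride used when generating
#'   liftoff events (continuous contact requires > 0.5).
#' @param seed integer seed for the sensor-noise stream.
#' @param oversample internal integration substeps per output sample
#'   (fixed-step 4th-order Runge-Kutta runs at `oversample * sample_rate`).
#'
#' @return An object of class `sim_config` (a named list).
#' @seealso [simulate_pendulum_trial()], [sensor_model()]
#' @export
#' @examples
#' cfg <- sim_config(L = 1.2, mass = 80, n_strides = 2)
#' cfg$amplitude0   # geometry-matched default
sim_config <- function(L = 1.2,
                       mass = 82.87,
                       amplitude0 = NULL,
                       damping = 0,
                       drive_impulse = 0,
                       ml_sway_amplitude = 0,
                       ml_sway_phase = 0,
                       n_strides = 2,
                       inter_bar_distance = 0.135,
                       sample_rate = 100,
                       noise_sd = 0,
                       orientation = c(0, 0, 0),
                       orientation_drift = c(0, 0, 0),
                       duty_factor = 0.71,
                       seed = NULL,
                       oversample = 10) {
  stopifnot(is.numeric(L), length(L) == 1L, is.finite(L), L > 0)
  stopifnot(is.numeric(mass), length(mass) == 1L, mass > 0)
  stopifnot(is.numeric(sample_rate), sample_rate > 0)
  stopifnot(is.numeric(n_strides), n_strides >= 1)
  stopifnot(is.numeric(inter_bar_distance), inter_bar_distance > 0)
  stopifnot(damping >= 0, drive_impulse >= 0, noise_sd >= 0)
  stopifnot(length(orientation) == 3L, length(orientation_drift) == 3L)
  stopifnot(duty_factor > 0, duty_factor <= 1)
  stopifnot(oversample >= 10)
  oversample <- as.integer(oversample)
  # even substep count so the half-sample node falls exactly mid-interval
  if (oversample %% 2L == 1L) oversample <- oversample + 1L
  if (is.null(amplitude0)) {
    amplitude0 <- asin(min(1, inter_bar_distance / (2 * L)))
  }
  stopifnot(is.numeric(amplitude0), length(amplitude0) == 1L,
            amplitude0 >= 0, amplitude0 < pi / 2)
  structure(
    list(L = L, mass = mass, amplitude0 = amplitude0, damping = damping,
         drive_impulse = drive_impulse,
         ml_sway_amplitude = ml_sway_amplitude,
         ml_sway_phase = ml_sway_phase,
         n_strides = as.integer(n_strides),
         inter_bar_distance = inter_bar_distance,
         sample_rate = sample_rate, noise_sd = noise_sd,
         orientation = as.numeric(orientation),
         orientation_drift = as.numeric(orientation_drift),
         duty_factor = duty_factor,
         seed = seed, oversample = as.integer(oversample)),
    class = "sim_config")
}

#' Exact period of a simple nonlinear pendulum
#'
#' Full (amplitude-dependent) oscillation period of an undamped simple
#' pendulum, `T = 4 sqrt(L/g) K(sin^2(theta0/2))` with `K` the complete
#' elliptic integral of the first kind. Reduces to `2 pi sqrt(L/g)` as the
#' amplitude tends to zero.
#'
#' @param L pendulum length, m.
#' @param amplitude swing amplitude, rad in `[0, pi/2)`.
#' @param g gravitational acceleration, m/s^2.
#' @return Period in seconds.
#' @export
#' @examples
#' pendulum_period(1, 0)                       # small-angle limit 2.006 s
#' pendulum_period(1, 30 * pi / 180) / pendulum_period(1, 0)  # ~1.017
pendulum_period <- function(L, amplitude = 0, g = G_ACCEL) {
  stopifnot(L > 0, amplitude >= 0, amplitude < pi / 2)
  if (amplitude == 0) return(2 * pi * sqrt(L / g))
  m <- sin(amplitude / 2)^2
  4 * sqrt(L / g) * pracma::ellipke(m)$k
}

# angular acceleration of the damped pendulum
.theta_ddot <- function(theta, omega, L, damping, g = G_ACCEL) {
  -(g / L) * sin(theta) - damping * omega
}

# one classical RK4 step of the (theta, omega) state
.rk4_step <- function(state, dt, L, damping) {
  f <- function(s) c(s[2], .theta_ddot(s[1], s[2], L, damping))
  k1 <- f(state)
  k2 <- f(state + dt / 2 * k1)
  k3 <- f(state + dt / 2 * k2)
  k4 <- f(state + dt * k3)
  state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Simulate one continuous-contact brachiation trial
#'
#' Integrates the damped pendulum `theta'' = -(g/L) sin(theta) -
#' damping * theta'` with a fixed-step 4th-order Runge-Kutta scheme at
#' `oversample` times the output rate, then reports state on the output grid.
#' The full `sin(theta)` nonlinearity is kept so the amplitude dependence of
#' the period is faithful. A handhold exchange fires at each forward apex
#' (angular velocity crossing zero with positive angle): the pivot advances
#' by `inter_bar_distance`, the angle flips sign, and `drive_impulse` is
#' added to the angular velocity. With the geometry-matched default
#' amplitude the exchange is position- and energy-continuous (a point
#' transition); exchanges alternate limbs, so one reference-limb stride
#' spans two exchanges.
#'
#' The COM position is `pivot + L (sin(theta), 0, -cos(theta))` plus the
#' mediolateral sway sinusoid; velocity and acceleration are the analytic
#' derivatives of that expression (using the equation of motion for
#' `theta''`), so the truth channels are free of numerical differentiation
#' noise.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `brach_truth`: a list with elements
#'   `time` (s), `position`, `velocity`, `acceleration` (n x 3 matrices with
#'   columns `x`, `y`, `z`), `velocity_half` (COM velocity at half-sample
#'   nodes, the sensor front end's support channel), `energy` (total
#'   mechanical energy, J, with the
#'   potential datum at the bottom of the arc), `stride_events`
#'   (data.frame: `limb`, `touchdown_s`, `liftoff_s`, `next_touchdown_s`),
#'   and `config`.
#' @export
#' @examples
#' tr <- simulate_pendulum_trial(sim_config(L = 1, n_strides = 2))
#' range(tr$energy) # conserved for the undamped, undriven default
simulate_pendulum_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- G_ACCEL
  L <- config$L
  sr <- config$sample_rate
  dt_out <- 1 / sr
  dt <- dt_out / config$oversample
  T_ref <- pendulum_period(L, config$amplitude0, g)
  n_exchanges_needed <- 2L * config$n_strides
  max_time <- (n_exchanges_needed + 4) * T_ref

  theta <- -config$amplitude0
  omega <- if (config$amplitude0 > 0) config$drive_impulse else 0
  pivot_x <- 0
  exchange_times <- numeric(0)

  n_max <- ceiling(max_time * sr) + 2L
  theta_s <- omega_s <- pivot_s <- numeric(n_max)
  theta_h <- omega_h <- numeric(n_max)  # state at half-sample nodes t_k - h/2
  theta_s[1] <- theta; omega_s[1] <- omega; pivot_s[1] <- pivot_x
  half_at <- config$oversample %/% 2L

  i <- 1L
  t <- 0
  while (i < n_max) {
    # advance one output sample with event handling on the micro grid
    for (k in seq_len(config$oversample)) {
      prev <- c(theta, omega)
      new <- .rk4_step(prev, dt, L, config$damping)
      if (prev[2] > 0 && new[2] <= 0 && new[1] > 0) {
        # forward apex crossed inside this micro step: locate it, flip
        alpha <- prev[2] / (prev[2] - new[2])
        apex <- .rk4_step(prev, alpha * dt, L, config$damping)
        if (apex[1] >= pi / 2) {
          stop(sprintf("over-rotation: amplitude reached pi/2 near t = %.4f s",
                       t + (k - 1 + alpha) * dt))
        }
        pivot_x <- pivot_x + config$inter_bar_distance
        exchange_times <- c(exchange_times,
                            t + (k - 1 + alpha) * dt)
        apex[1] <- -apex[1]
        apex[2] <- config$drive_impulse
        new <- .rk4_step(apex, (1 - alpha) * dt, L, config$damping)
      }
      if (!all(is.finite(new))) {
        stop(sprintf("integration failure: non-finite state at t = %.4f s",
                     t + k * dt))
      }
      if (abs(new[1]) >= pi / 2) {
        stop(sprintf("over-rotation: amplitude reached pi/2 near t = %.4f s",
                     t + k * dt))
      }
      theta <- new[1]; omega <- new[2]
      if (k == half_at) { theta_h[i + 1L] <- theta; omega_h[i + 1L] <- omega }
    }
    t <- i * dt_out
    i <- i + 1L
    theta_s[i] <- theta; omega_s[i] <- omega; pivot_s[i] <- pivot_x
    done <- length(exchange_times) >= n_exchanges_needed &&
      t >= exchange_times[n_exchanges_needed]
    if (done || t >= max_time) break
  }

  n <- i
  time <- (seq_len(n) - 1L) * dt_out
  theta_s <- theta_s[seq_len(n)]
  omega_s <- omega_s[seq_len(n)]
  pivot_s <- pivot_s[seq_len(n)]
  alpha_s <- .theta_ddot(theta_s, omega_s, L, config$damping)

  # mediolateral sway at the stride frequency implied by the swing amplitude
  f_ml <- 1 / T_ref
  A <- config$ml_sway_amplitude
  phy <- config$ml_sway_phase
  wml <- 2 * pi * f_ml
  y <- A * sin(wml * time + phy)
  vy <- A * wml * cos(wml * time + phy)
  ay <- -A * wml^2 * sin(wml * time + phy)

  position <- cbind(x = pivot_s + L * sin(theta_s),
                    y = y,
                    z = -L * cos(theta_s))
  velocity <- cbind(x = L * omega_s * cos(theta_s),
                    y = vy,
                    z = L * omega_s * sin(theta_s))
  acceleration <- cbind(
    x = L * (alpha_s * cos(theta_s) - omega_s^2 * sin(theta_s)),
    y = ay,
    z = L * (alpha_s * sin(theta_s) + omega_s^2 * cos(theta_s)))

  energy <- config$mass * g * (position[, "z"] + L) +
    0.5 * config$mass * rowSums(velocity^2)

  # COM velocity at half-sample nodes t_k - h/2 (k >= 2): support channel for
  # the sensor's integrate-and-decimate front end (see sensor_model)
  th <- theta_h[seq_len(n)]; oh <- omega_h[seq_len(n)]
  t_half <- time - dt_out / 2
  velocity_half <- cbind(x = L * oh * cos(th),
                         y = A * wml * cos(wml * t_half + phy),
                         z = L * oh * sin(th))
  velocity_half[1, ] <- NA_real_

  touchdowns <- c(0, exchange_times)
  limbs <- rep(c("left", "right"), length.out = length(touchdowns))
  next_td <- c(touchdowns[-(1:2)], NA_real_, NA_real_)[seq_along(touchdowns)]
  liftoff <- touchdowns + config$duty_factor * (next_td - touchdowns)
  stride_events <- data.frame(limb = limbs,
                              touchdown_s = touchdowns,
                              liftoff_s = liftoff,
                              next_touchdown_s = next_td)

  structure(list(time = time, position = position, velocity = velocity,
                 acceleration = acceleration, velocity_half = velocity_half,
                 energy = energy, stride_events = stride_events,
                 config = config),
            class = "brach_truth")
}

#' @exportS3Method base::print
print.brach_truth <- function(x, ...) {
  ns <- sum(!is.na(x$stride_events$next_touchdown_s))
  cat(sprintf(
    "<brach_truth> %d samples @ %g Hz, %.2f s, %d complete strides\n",
    length(x$time), x$config$sample_rate, max(x$time), ns))
  invisible(x)
}

#' Rotation matrix from intrinsic Z-Y-X (yaw-pitch-roll) Euler angles
#'
#' Builds the local-to-global rotation `R = Rz(yaw) %*% Ry(pitch) %*%
#' Rx(roll)` (intrinsic Tait-Bryan Z-Y-X convention).
#'
#' @param roll,pitch,yaw angles in rad.
#' @return A 3 x 3 rotation matrix.
#' @export
#' @examples
#' euler_to_matrix(0, 0, 0)        # identity
euler_to_matrix <- function(roll, pitch, yaw) {
  cr <- cos(roll); sr <- sin(roll)
  cp <- cos(pitch); sp <- sin(pitch)
  cy <- cos(yaw); sy <- sin(yaw)
  matrix(c(
    cy * cp, cy * sp * sr - sy * cr, cy * sp * cr + sy * sr,
    sy * cp, sy * sp * sr + cy * cr, sy * sp * cr - cy * sr,
    -sp,     cp * sr,                cp * cr), nrow = 3, byrow = TRUE)
}

#' Synthesize a triaxial accelerometer trace from a simulated trial
#'
#' Models the waist-mounted sensor: the local-frame specific force is
#' `t(R) %*% (a_global - g_vec)` with `g_vec = (0, 0, -9.81)` m/s^2 and `R`
#' the mounting rotation (optionally drifting slowly over the trial), plus
#' zero-mean Gaussian noise of standard deviation `noise_sd`. The Euler-angle
#' channels report the mounting angles (plus drift), i.e. the orientation
#' the onboard fusion would output.
#'
#' Consumer MEMS accelerometers integrate and decimate internally, so with
#' the default `sampling = "average"` each output sample is the average
#' specific force over the centred sample window
#' `[t_k - h/2, t_k + h/2]` (computed exactly from the simulator's
#' half-sample COM velocities). This matters at handhold exchanges, where
#' the global acceleration has a finite jump: averaging preserves the
#' velocity integral through the jump, while `sampling = "instantaneous"`
#' (point samples of the truth acceleration) leaves a per-exchange
#' integration error of order `dt` in downstream double integration.
#'
#' @param truth a `brach_truth` object from [simulate_pendulum_trial()].
#' @param config the trial's [sim_config()]; defaults to `truth$config`.
#' @param sampling `"average"` (integrate-and-decimate front end, default)
#'   or `"instantaneous"` (point samples).
#' @return An [imu_trace()] object.
#' @export
#' @examples
#' tr <- simulate_pendulum_trial(sim_config(n_strides = 1, seed = 1))
#' imu <- sensor_model(tr)
sensor_model <- function(truth, config = truth$config,
                         sampling = c("average", "instantaneous")) {
  stopifnot(inherits(truth, "brach_truth"), inherits(config, "sim_config"))
  sampling <- match.arg(sampling)
  n <- length(truth$time)
  h <- 1 / config$sample_rate
  if (sampling == "average" && !is.null(truth$velocity_half) && n >= 3) {
    vh <- truth$velocity_half
    a_glob <- truth$acceleration
    a_glob[1, ] <- (vh[2, ] - truth$velocity[1, ]) / (h / 2)
    a_glob[n, ] <- (truth$velocity[n, ] - vh[n, ]) / (h / 2)
    mid <- 2:(n - 1)
    a_glob[mid, ] <- (vh[mid + 1L, ] - vh[mid, ]) / h
  } else {
    a_glob <- truth$acceleration
  }
  ang <- matrix(rep(config$orientation, each = n), ncol = 3) +
    outer(truth$time, config$orientation_drift)
  colnames(ang) <- c("roll", "pitch", "yaw")
  g_vec <- c(0, 0, -G_ACCEL)
  local <- matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  for (i in seq_len(n)) {
    R <- euler_to_matrix(ang[i, 1], ang[i, 2], ang[i, 3])
    local[i, ] <- crossprod(R, a_glob[i, ] - g_vec)
  }
  if (config$noise_sd > 0) {
    if (!is.null(config$seed)) set.seed(config$seed)
    local <- local + matrix(rnorm(3L * n, sd = config$noise_sd), n, 3)
  }
  imu_trace(time = truth$time, acceleration = local, euler = ang,
            sample_rate = config$sample_rate)
}

#' Simulate a brachiation cohort with ground truth
#'
#' Draws `n_subjects` sets of anthropometrics spanning the observed human
#' ranges (height 1.68-1.93 m, mass 65-103 kg, forelimb/height 0.39-0.44,
#' grip/weight 0.36-0.77, contact-to-COM length L 1.10-1.43 m) and, for each
#' subject, a set of trials simulated with subject-specific pendulum length,
#' damping and handhold drive. Damping and drive ranges are chosen so the
#' realized mechanical-energy recovery of the cohort spans roughly the
#' observed human range (about 15-40%). Ground truth is retained for every
#' trial so parameter-recovery tests can compare reconstruction to truth.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param trials_per_subject trials per subject (default 5, the minimum
#'   number of runs each participant contributed).
#' @param strides_per_trial complete reference-limb strides per trial
#'   (default 2, a short-runway traversal).
#' @param seed integer seed governing all draws.
#' @param noise_sd sensor noise passed to each trial, m/s^2.
#' @return A list with `anthropometrics` (data.frame, one row per subject)
#'   and `trials` (list of lists with `subject`, `trial`, `config`, `truth`,
#'   `imu`).
#' @export
simulate_cohort <- function(n_subjects = 9, trials_per_subject = 5,
                            strides_per_trial = 2, seed = 1,
                            noise_sd = 0.1) {
  stopifnot(n_subjects >= 1, trials_per_subject >= 1)
  set.seed(seed)
  height <- runif(n_subjects, 1.68, 1.93)
  mass <- runif(n_subjects, 65, 103)
  flr <- runif(n_subjects, 0.39, 0.44)
  grip_ratio <- runif(n_subjects, 0.36, 0.77)
  L <- runif(n_subjects, 1.10, 1.43)
  damping <- runif(n_subjects, 1.5, 3.0)
  drive <- runif(n_subjects, 0.3, 0.8)
  sway <- runif(n_subjects, 0.05, 0.2)
  anthro <- data.frame(
    subject = seq_len(n_subjects),
    height_m = height, mass_kg = mass,
    forelimb_m = flr * height, forelimb_height = flr,
    grip_force_kg = grip_ratio * mass, grip_weight = grip_ratio,
    L_m = L, damping = damping, drive = drive)
  trial_seeds <- sample.int(.Machine$integer.max - 1L,
                            n_subjects * trials_per_subject)
  trials <- vector("list", n_subjects * trials_per_subject)
  idx <- 0L
  for (s in seq_len(n_subjects)) {
    for (tr in seq_len(trials_per_subject)) {
      idx <- idx + 1L
      cfg <- sim_config(
        L = L[s], mass = mass[s],
        damping = damping[s] * runif(1, 0.9, 1.1),
        drive_impulse = drive[s] * runif(1, 0.9, 1.1),
        ml_sway_amplitude = sway[s] * runif(1, 0.8, 1.2),
        ml_sway_phase = runif(1, 0, 2 * pi),
        n_strides = strides_per_trial,
        noise_sd = noise_sd,
        seed = trial_seeds[idx])
      truth <- simulate_pendulum_trial(cfg)
      trials[[idx]] <- list(subject = s, trial = tr, config = cfg,
                            truth = truth, imu = sensor_model(truth))
    }
  }
  list(anthropometrics = anthro, trials = trials)
}
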