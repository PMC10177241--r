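#' Translational kinetic energy
#'
#' `EK = m v^2 / 2`, applied per axis to the COM velocity.
#'
#' @param mass body mass, kg (> 0).
#' @param velocity COM velocity, m/s (vectorized).
#' @return Kinetic energy, J.
#' @export
#' @examples
#' kinetic_energy(80, 0.6)  # 14.4 J
kinetic_energy <- function(mass, velocity) {
  stopifnot(mass > 0)
  0.5 * mass * velocity^2
}

#' Gravitational potential energy
#'
#' `EP = m g h` with g = 9.81 m/s^2 and `h` the vertical displacement of
#' the COM above the chosen datum (here the stride's lowest point).
#'
#' @param mass body mass, kg (> 0).
#' @param h vertical displacement, m (vectorized).
#' @param g gravitational acceleration, m/s^2.
#' @return Potential energy, J.
#' @export
#' @examples
#' potential_energy(80, 0.10)  # 78.48 J
potential_energy <- function(mass, h, g = G_ACCEL) {
  stopifnot(mass > 0)
  mass * g * h
}

# sum of positive sample-to-sample increments of a series
positive_increments <- function(x) {
  sum(pmax(diff(x), 0))
}

#' Cavagna-style percent recovery of mechanical energy
#'
#' Pendular effectiveness over one stride:
#' `recovery = 100 * (dEK + dEP - dET) / (dEK + dEP)`, where each `d` term
#' is the sum of the positive sample-to-sample increments of the kinetic,
#' potential and total (`ET = EK + EP`) energy profiles. A perfect
#' out-of-phase exchange gives 100%, fully in-phase profiles give 0%.
#' Increments are computed on the raw processed grid without smoothing,
#' and the statistic is invariant to the potential-energy datum (only
#' increments enter).
#'
#' @param EK_total total kinetic energy series, J.
#' @param EP potential energy series on the same grid, J.
#' @return A list of class `recovery_result`: `percent_recovery` (%),
#'   `delta_EK`, `delta_EP`, `delta_ET` (J).
#' @export
#' @examples
#' percent_recovery(c(0, 2, 1, 3), c(1, 0, 2, 1))$percent_recovery # 400/7
percent_recovery <- function(EK_total, EP) {
  stopifnot(length(EK_total) == length(EP), length(EP) >= 2,
            all(is.finite(EK_total)), all(is.finite(EP)))
  dEK <- positive_increments(EK_total)
  dEP <- positive_increments(EP)
  dET <- positive_increments(EK_total + EP)
  if (dEK + dEP == 0) {
    stop("undefined recovery: energy profiles are flat (no positive increments)")
  }
  structure(list(percent_recovery = 100 * (dEK + dEP - dET) / (dEK + dEP),
                 delta_EK = dEK, delta_EP = dEP, delta_ET = dET),
            class = "recovery_result")
}

#' @exportS3Method base::print
print.recovery_result <- function(x, ...) {
  cat(sprintf("recovery %.2f%% (dEK %.3g J, dEP %.3g J, dET %.3g J)\n",
              x$percent_recovery, x$delta_EK, x$delta_EP, x$delta_ET))
  invisible(x)
}

#' Expected small-angle pendular period
#'
#' `T = 2 pi sqrt(L / g)`: the period of a simple pendulum of length `L`
#' (contact point to COM). Amplitude does not enter the formula.
#'
#' @param L pendulum length, m (> 0).
#' @param g gravitational acceleration, m/s^2.
#' @return Period, s.
#' @export
#' @examples
#' expected_period(0.9942)  # 2.000 s
expected_period <- function(L, g = G_ACCEL) {
  stopifnot(all(L > 0))
  2 * pi * sqrt(L / g)
}

#' Observed pendular period from stride events
#'
#' Operationalized as the mean stride duration (touchdown to next
#' touchdown of the same limb): one stride corresponds to one full swing
#' cycle of the body pendulum.
#'
#' @param events a [stride_events()] table or any data.frame with
#'   `touchdown_s` and `next_touchdown_s`.
#' @return Mean stride duration, s.
#' @export
#' @examples
#' observed_period(stride_events("left", 0, 0.62, 0.94))  # 0.94 s
observed_period <- function(events) {
  d <- events$next_touchdown_s - events$touchdown_s
  d <- d[!is.na(d)]
  if (length(d) == 0) stop("no complete strides in events table")
  mean(d)
}

#' Mediolateral and vertical COM excursions within a stride
#'
#' Range (max - min) of the mediolateral and vertical COM positions over
#' the stride window.
#'
#' @param position n x 3 matrix of COM positions (columns x, y, z), m.
#' @param window optional index vector selecting the stride window.
#' @return List with `ml_excursion_m` and `vertical_excursion_m`.
#' @export
excursions <- function(position, window = NULL) {
  position <- as.matrix(position)
  if (!is.null(window)) position <- position[window, , drop = FALSE]
  stopifnot(nrow(position) >= 1, ncol(position) == 3)
  list(ml_excursion_m = diff(range(position[, 2])),
       vertical_excursion_m = diff(range(position[, 3])))
}

#' Per-axis mechanical-energy profile of a stride
#'
#' Assembles fore-aft, mediolateral and normal (vertical) kinetic energies,
#' potential energy (datum: the stride's minimum vertical position), their
#' total kinetic energy and total energy `ET = EK + EP` on the stride grid.
#'
#' @param kin a `global_kinematics` object (one stride window), or any list
#'   with `time`, `velocity`, `position`.
#' @param mass body mass, kg.
#' @return A data.frame with columns `time_s`, `EK_x`, `EK_y`, `EK_z`,
#'   `EK_total`, `EP`, `ET`, `h_m`.
#' @export
energy_profile <- function(kin, mass) {
  if (missing(mass) || is.null(mass) || !is.numeric(mass)) {
    stop("mass (kg) is required to build an energy profile")
  }
  stopifnot(mass > 0)
  v <- kin$velocity
  z <- kin$position[, 3]
  h <- z - min(z)
  EK <- kinetic_energy(mass, v)
  EK_total <- rowSums(EK)
  EP <- potential_energy(mass, h)
  data.frame(time_s = kin$time,
             EK_x = EK[, 1], EK_y = EK[, 2], EK_z = EK[, 3],
             EK_total = EK_total, EP = EP, ET = EK_total + EP, h_m = h)
}

#' Per-stride energetic and pendular summary
#'
#' Combines [energy_profile()], [percent_recovery()], [excursions()] and
#' the period comparison into one tidy row per stride.
#'
#' @param kin a `global_kinematics` object spanning one stride.
#' @param mass body mass, kg.
#' @param L pendulum length (contact point to COM), m.
#' @param stride_time_s observed stride duration, s.
#' @return One-row data.frame: `recovery_pct`, `delta_EK_J`, `delta_EP_J`,
#'   `delta_ET_J`, `ml_excursion_m`, `vertical_excursion_m`,
#'   `observed_period_s`, `expected_period_s`.
#' @export
stride_energetics <- function(kin, mass, L, stride_time_s) {
  prof <- energy_profile(kin, mass)
  rec <- percent_recovery(prof$EK_total, prof$EP)
  exc <- excursions(kin$position)
  data.frame(recovery_pct = rec$percent_recovery,
             delta_EK_J = rec$delta_EK, delta_EP_J = rec$delta_EP,
             delta_ET_J = rec$delta_ET,
             ml_excursion_m = exc$ml_excursion_m,
             vertical_excursion_m = exc$vertical_excursion_m,
             observed_period_s = stride_time_s,
             expected_period_s = expected_period(L))
}
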