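# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the elliptic integral is evaluated by adaptive
# quadrature, positive increments by an explicit loop, least squares by lm().

# complete elliptic integral of the first kind, K(m), by quadrature
quad_elliptic_K <- function(m) {
  stats::integrate(function(u) 1 / sqrt(1 - m * sin(u)^2), 0, pi / 2,
                   rel.tol = 1e-10)$value
}

# amplitude-dependent pendulum period from the quadrature oracle
oracle_period <- function(L, amplitude, g = 9.81) {
  4 * sqrt(L / g) * quad_elliptic_K(sin(amplitude / 2)^2)
}

# sum of positive increments by explicit enumeration
oracle_positive_increments <- function(x) {
  s <- 0
  for (i in seq_along(x)[-1]) {
    d <- x[i] - x[i - 1]
    if (d > 0) s <- s + d
  }
  s
}

# recovery statistic assembled only from the enumeration oracle
oracle_recovery <- function(EK, EP) {
  dEK <- oracle_positive_increments(EK)
  dEP <- oracle_positive_increments(EP)
  dET <- oracle_positive_increments(EK + EP)
  100 * (dEK + dEP - dET) / (dEK + dEP)
}

# observed stride period of a simulated trial (mean touchdown-to-touchdown
# interval of the same limb, i.e. twice the exchange interval)
trial_period <- function(truth) {
  ev <- truth$stride_events
  ev <- ev[!is.na(ev$next_touchdown_s), ]
  mean(ev$next_touchdown_s - ev$touchdown_s)
}

# per-stride RMS position error of the reconstruction chain
# (sensor -> rotation -> double integration), against the truth channel
roundtrip_rms_mm <- function(cfg) {
  truth <- simulate_pendulum_trial(cfg)
  imu <- sensor_model(truth)
  ev <- truth$stride_events[!is.na(truth$stride_events$next_touchdown_s), ]
  half <- 0.5 / cfg$sample_rate
  vapply(seq_len(nrow(ev)), function(i) {
    idx <- which(truth$time >= ev$touchdown_s[i] + half - 1e-9 &
                   truth$time < ev$next_touchdown_s[i] - half - 1e-9)
    v0 <- truth$velocity[idx[1], 1]
    kin <- process_trial(imu, ev[i, , drop = FALSE], v0)[[1]]
    truth_rel <- sweep(truth$position[idx, , drop = FALSE], 2,
                       truth$position[idx[1], ])
    sqrt(mean((kin$position - truth_rel)^2)) * 1000
  }, numeric(1))
}
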