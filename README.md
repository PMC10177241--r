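# brachiate

Centre-of-mass (COM) mechanics of continuous-contact brachiation —
arm-swinging suspensory locomotion — reconstructed from waist-mounted
triaxial accelerometry and high-speed video.

Brachiating animals are often idealized as passive pendulums: the body
swings below the handhold, trading potential for kinetic energy so that
little muscular work is needed. This package provides the full analysis
chain used to test that idealization in a cohort of brachiating subjects,
together with a ground-truthed simulator so every processing stage can be
validated without recordings. It is aimed at comparative biomechanists and
locomotor-energetics researchers working with consumer IMU + video setups.

## The quantities at its core

For a subject of mass *m*, the per-axis kinetic energy of the COM is
*EK = ½ m v²* (fore-aft, mediolateral, vertical), the potential energy is
*EP = m g h* with *h* the vertical COM displacement above the stride's
lowest point, and the total energy is *ET = EK + EP*. Pendular
effectiveness over a stride is the Cavagna-style **percent recovery**

    recovery (%) = 100 · (ΔEK + ΔEP − ΔET) / (ΔEK + ΔEP)

where each Δ is the sum of the *positive increments* of the corresponding
profile: 100 % for a perfect out-of-phase exchange, 0 % for fully in-phase
profiles. The pendular prediction itself is the period law
*T = 2π √(L/g)*, with *L* the distance from the handhold to the COM;
the observed period is the stride duration. Candidate anatomical and
behavioural predictors of recovery (fore-aft speed, forelimb/height ratio,
body mass, mediolateral and vertical excursions, grip/weight ratio) are
ranked by fitting all 64 fixed-effect subsets as rank-transformed linear
mixed models (random intercept per subject, maximum likelihood), retaining
models with ΔAIC < 3, and summing Akaike weights per predictor.

## Worked example

Simulate one damped, driven brachiation trial, pass it through the sensor
model and the IMU pipeline, and summarize the first stride:

```r
library(brachiate)

cfg <- sim_config(L = 1.2, mass = 80, damping = 2, drive_impulse = 0.5,
                  ml_sway_amplitude = 0.1, n_strides = 2,
                  noise_sd = 0.1, seed = 42)
truth <- simulate_pendulum_trial(cfg)
imu   <- sensor_model(truth)

ev  <- truth$stride_events[!is.na(truth$stride_events$next_touchdown_s), ]
td1 <- which.min(abs(truth$time - (ev$touchdown_s[1] + 0.005)))
kin <- process_trial(imu, ev[1, ], v0_foreaft = truth$velocity[td1, 1])[[1]]
stride_energetics(kin, mass = 80, L = 1.2,
                  stride_time_s = ev$next_touchdown_s[1] - ev$touchdown_s[1])
#>   recovery_pct delta_EK_J delta_EP_J delta_ET_J ml_excursion_m
#> 1       31.818     14.331      6.101     13.931          0.115
#>   vertical_excursion_m observed_period_s expected_period_s
#> 1                0.005             1.232             2.198
```

A heavily damped, shoulder-driven swing recovers only ~32 % of its
mechanical energy, and its observed stride period (1.23 s) is far below
the passive-pendulum prediction for its arm length (2.20 s) — the
signature of muscularly forced brachiation.

Cohort summaries pool the bundled per-subject table (means ± SD per
individual with stride counts), stride-count-weighted for stride-level
variables:

```r
gs <- grand_summary(load_table1_fixture())
subset(gs, variable %in% c("recovery_pct", "period_s", "predicted_period_s"))
#>              variable pooling    mean sd_sample sd_population
#> 7        recovery_pct  stride 29.8062   11.2827       11.2120
#> 8            period_s  stride  1.2271    0.2507        0.2492
#> 17 predicted_period_s subject  2.2089    0.1006        0.0948
```

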