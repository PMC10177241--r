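---
title: "Pendular mechanics of brachiation: models, pipeline and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pendular mechanics of brachiation: models, pipeline and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brachiate)
```

## The scientific model

Slow, continuous-contact brachiation keeps at least one hand on the
substrate at all times (duty factor > 0.5), and the body's centre of mass
(COM) traces a sequence of circular arcs below successive handholds. If
the motion were purely pendular, potential and kinetic energy would
interchange out of phase and the swing period would follow
$T = 2\pi\sqrt{L/g}$, where $L$ is the handhold-to-COM distance and
$g = 9.81\,\mathrm{m/s^2}$. This package quantifies how closely real (or
simulated) brachiation approaches that ideal through three lenses:

1. **Percent recovery** — for per-stride profiles of total kinetic energy
   $E_K$ and potential energy $E_P$ (with $E_T = E_K + E_P$),
   $\mathrm{recovery} = 100\,(\Delta E_K + \Delta E_P - \Delta E_T) /
   (\Delta E_K + \Delta E_P)$, each $\Delta$ being the sum of positive
   sample-to-sample increments. The statistic is invariant to the $E_P$
   datum and bounded in $[0, 100]$ by subadditivity of positive
   increments.
2. **Observed versus expected period** — the observed period is
   operationalized as the stride duration (same-limb touchdown to
   touchdown). For the per-subject summary rows bundled with the package,
   printed stance + swing sums reproduce the printed periods, which is
   what fixes this reading; a swept-arc half-period would be an
   alternative, and is the one known ambiguity in the period comparison.
3. **Predictor ranking** — energy recovery is modelled against six
   candidate fixed effects (fore-aft speed, forelimb/height ratio, body
   mass, mediolateral and vertical excursions, grip/weight ratio) with a
   random intercept per subject; all $2^6 = 64$ subsets are fitted and
   compared by AIC.

## The synthetic-trial generator

`simulate_pendulum_trial()` integrates the damped pendulum
$\ddot\theta = -(g/L)\sin\theta - c\,\dot\theta$ with a fixed-step
classical Runge–Kutta scheme running at `oversample` (≥ 10, forced even)
substeps per output sample. The full $\sin\theta$ nonlinearity is kept so
that the amplitude dependence of the period — the basis of the
expected-versus-observed comparison — is faithful rather than assumed
away. On a 1 kHz grid, undamped undriven trials conserve total mechanical
energy to well below $10^{-6}$ relative (the suite checks this), and the
simulated period matches the elliptic-integral period to better than 0.1 %.

**Handhold exchange.** The exchange is modelled as an instantaneous event
at the forward apex of the swing (angular velocity crossing zero at
positive angle): the pivot advances by one inter-bar distance $d$
(default 0.135 m, the rung spacing of the experimental runway), the
pendulum angle flips sign, and a `drive_impulse` (rad/s) — the muscular
boost from the shoulder — is added to the angular velocity. The default
amplitude is the geometry-matched $\theta_0 = \arcsin(d/2L)$, for which
the flip is position- and energy-continuous (the classic point
transition, with a velocity-free cusp at the apex). At other amplitudes a
small fore-aft discontinuity remains at each exchange, which we read as
hand repositioning ("slip") at capture; the energy channel is unaffected
because $|\theta|$ and $\dot\theta$ are preserved. The event time is
located inside a substep by linear interpolation of the angular velocity,
so exchange timing is resolved well below the integration step.

**Mediolateral sway** is a kinematic sinusoid at the stride frequency
implied by the swing amplitude, superimposed on the planar pendulum. Real
sway is dynamic; modelling it kinematically adds the observed ML
excursions and their kinetic-energy fluctuations without coupling back
into the swing. Because it is kinematic, trials with sway do not conserve
the reported total energy exactly — conservation holds for the planar
pendulum, which is how the conservation property is tested.

**Sensor model.** `sensor_model()` emits local-frame specific force
$R^\top(a - g_{vec})$ under a configurable mounting rotation (intrinsic
Z–Y–X Euler angles, optionally drifting linearly), plus white Gaussian
noise. Consumer MEMS accelerometers integrate and decimate internally, so
the default output sample is the *average* specific force over the
centred sample window, computed exactly from the simulator's half-sample
velocities. This detail matters: the global acceleration has a finite
jump at each exchange, and point sampling would leave an integration
error of order $\Delta a \cdot \Delta t$ (2–5 mm per stride at 100 Hz) in
any quadrature of the samples, misrepresenting what a real decimating
sensor records. Instantaneous sampling remains available via
`sampling = "instantaneous"`.

**Cohort generator.** `simulate_cohort()` draws anthropometrics uniformly
over the observed human ranges (height 1.68–1.93 m, mass 65–103 kg,
forelimb/height 0.39–0.44, grip/weight 0.36–0.77, $L$ 1.10–1.43 m — the
$L$ range is implied by the observed predicted periods). Per-subject
damping and drive are drawn from $c \sim U(1.5, 3.0)\,\mathrm{s^{-1}}$
and $U(0.3, 0.8)\,\mathrm{rad/s}$: across these ranges the realized
per-subject mechanical recovery spans roughly 10–45 %, bracketing the
observed human span (≈ 16–37 %), with damping the dominant knob
(recovery falls monotonically with damping at fixed drive). Sensor
defaults — 100 Hz sampling and 0.1 m/s² noise — are typical of the
consumer sensor class used for such recordings; neither is reported for
the original hardware, so both are exposed in the configuration.

What the generator does **not** emulate: ricochetal (aerial-phase)
brachiation; double-support dynamics (the exchange is instantaneous, so
simulated duty factors are bookkeeping from a configurable contact
fraction, not emergent); trunk/limb inertia (vertical excursions are
$L(1-\cos\theta)$-scale, centimetres, whereas humans show tens of
centimetres from active body lifting); and dynamic mediolateral
mechanics. Passing tests therefore certify the *processing chain*, not
the realism of every human behaviour.

## The IMU processing chain

`to_global_frame()` rotates each sample by the intrinsic Z–Y–X
(yaw–pitch–roll) rotation built from the fused Euler channels and removes
gravity; the convention is fixed here because neither the sensor vendor
nor typical field protocols document one, and it is exposed through the
mounting configuration. `integrate_kinematics()` integrates by cumulative
trapezoid — second-order accuracy at no cost over the rectangle rule —
once to velocity and once to position.

**Integration constants.** The fore-aft constant comes from the
digitized head track: `estimate_initial_velocity()` takes the
least-squares slope of the last ten pre-touchdown frames (120 Hz video).
Only the fore-aft constant has an observable source; the mediolateral and
vertical constants are closed by the steady-state assumption that each
axis has zero mean velocity over a stride (equivalently, zero net
displacement per cycle). A zero-initial-velocity alternative is available
(`closure = "zero_start"`). In the simulator-backed pipeline the fore-aft
constant is taken from the truth channel, standing in for the head track.

**Detrending.** `detrend_acceleration()` removes a per-axis least-squares
line. It is *disabled by default* in `process_trial()`: over a window of
only one or two pendular cycles, a straight-line fit removes genuine
periodic signal (the least-squares slope of a sine-phase cycle is
nonzero), and re-integrating the clipped signal displaces the
reconstruction by tens of centimetres. Detrending earns its keep only
when slow sensor-bias drift dominates the fitted line, i.e. on long or
drift-contaminated recordings; it is kept as an explicit, tested step for
that regime.

**Stride windows** are closed–open `[touchdown, next touchdown)`,
trimmed by half a sample at each end so that every retained sample's
averaging window lies strictly inside the stride (the bounding exchanges
belong to the neighbouring strides). With zero noise the chain
simulator → sensor → rotation → double integration reproduces the truth
COM path to ≈ 0.6 mm RMS per stride at 100 Hz; with 0.1 m/s² sensor noise
the error stays below 1 cm.

## Energetics conventions

The potential-energy datum is the stride's minimum vertical position —
recovery is datum-invariant, so this choice only affects plotted absolute
values. Positive increments are computed sample-to-sample on the
processed grid without smoothing, because any low-pass step changes the
$\Delta$ sums and no filtering is part of the definition. Only complete
strides are analysed; trials with fewer than one full stride are
excluded. Excursions are positional ranges (max − min) per axis within
the stride.

## Cohort statistics

All candidate models are fitted by **maximum likelihood** (not REML):
AIC comparisons across different fixed-effect structures are only valid
under ML. Responses and predictors are rank-transformed unconditionally
(average ranks for ties, missing values propagated) before fitting, as a
distribution-free guard; normality screening is left to standard
routines. Missing grip measurements (one subject in the bundled table)
are dropped listwise only for models that include grip, so grip-free
models keep the full cohort. Singular fits — common when the subject
variance collapses under rank transformation — are retained with their
AIC and flagged rather than discarded, since dropping them would bias the
model set. Akaike weights are renormalized over the ΔAIC < 3 retained
set, and predictor importance is the sum of retained-model weights
containing the predictor; ties at the top of the importance ranking are
counted in favour of tied predictors when assessing rank recovery.

Grand summaries pool per-subject means stride-count-weighted for
stride-level variables — the only pooling rule under which the bundled
per-subject rows reproduce the published cohort means — and unweighted
across subjects for anthropometrics. Both the sample ($n-1$) and
population ($n$) SD conventions are emitted because the published
predicted-period spread follows the population convention while the other
spreads follow the sample one. Two published scalars are not exactly
recoverable from the bundled rows under any pooling (the grand grip/weight
ratio and the grand speed); the summaries report the recomputed values and
make the pooling explicit rather than matching those two numbers.

The synthetic statistics cohort (`simulate_recovery_cohort()`) generates
recovery from subject-level forelimb/height and grip/weight effects at
the magnitudes estimated in human brachiation (≈ 896 and 82 % per unit
ratio), a Gaussian random intercept (SD 2 %) and stride noise (SD 9 %),
with null stride-level covariates. The noise SDs were fixed once so that
cohorts of the observed size (9 subjects, 80 strides with the observed
per-subject counts) reproduce the clean importance separation seen in the
human data; at these settings the two true predictors top the importance
ranking in ≈ 95 % of seeds.

## Problem sizes and numerics

The test-suite simulations use 2–4 strides per trial at 100–1000 Hz with
tenfold Runge–Kutta oversampling — past the point where halving the step
changes any asserted quantity at its tolerance. The stochastic
rank-recovery property uses 50 seeds of 9 × 80-stride cohorts (64 mixed
models each), the natural scale for a cohort-level success rate.
Degenerate inputs are signalled, not silently handled: non-finite Euler
angles name the offending sample, non-uniform grids demand resampling,
over-rotation past π/2 aborts the simulation with the offending time, and
flat energy profiles make recovery undefined rather than zero.

## Known limitations

The pendulum is a point mass: inertial effects of swinging limbs are
outside the model, and the simulator cannot reproduce the mid-stride
kinetic-energy dip seen in human traces (active deceleration), only lower
recovery through damping plus apex drive. Event detection is not
automated — stride events come from video or from the simulator. The
accelerometer–video synchronization step is modelled as already-aligned
clocks. Conclusions about real recordings should lean on the validated
invariants (rotation fidelity, integration accuracy, statistic
definitions), not on the generator's behavioural realism.
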