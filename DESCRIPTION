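Package: brachiate
Title: Center-of-Mass Mechanics and Pendular Energetics of Brachiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the centre-of-mass (COM) mechanics of
    continuous-contact brachiation (arm-swinging suspensory locomotion).
    Reconstructs global COM kinematics from waist-mounted triaxial
    accelerometer streams (Euler-angle rotation, detrending, double
    integration with video-derived integration constants), computes
    spatiotemporal stride variables, Cavagna-style positive-increment
    mechanical-energy recovery, COM excursions, and observed versus
    expected simple-pendulum periods, and ranks anatomical and
    behavioural predictors of energy recovery with linear mixed-effect
    models, AIC differences, Akaike weights and predictor importance.
    Includes a driven, damped nonlinear-pendulum trial simulator and a
    cohort generator that provide ground-truthed synthetic recordings
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
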