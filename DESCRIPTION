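Package: coroUQ
Title: Personalized and Uncertainty-Aware Coronary Hemodynamics
Version: 0.1.0
Authors@R:
    person("coroUQ", "Developers", email = "corouq@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for personalized, uncertainty-aware
    simulation of coronary artery hemodynamics. Provides a closed-loop
    lumped-parameter (0D) circulation model with coronary outlet boundary
    conditions and time-varying elastance heart chambers; assignment of left
    ventricular perfusion territories to coronary outlets and integration of
    myocardial blood flow into branch-specific flow targets with a simulated
    noise model; Bayesian personalization of outlet resistances via a
    differential-evolution adaptive Metropolis (DREAM) sampler; clinical and
    biomechanical quantities of interest (fractional flow reserve,
    time-averaged wall shear stress, oscillatory shear index); and
    multi-fidelity Monte Carlo estimation with a shared-space resampling
    strategy based on supervised autoencoders linked through one-dimensional
    normalizing flows, which increases low/high-fidelity correlation and
    reduces estimator variance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
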