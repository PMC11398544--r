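---
title: "coroUQ methods: models, calibration, and multi-fidelity estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{coroUQ methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the models and
their assumptions, the parameters that matter, what the synthetic data
generator does and does not emulate, the numerical choices, and the known
limitations. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## 1. The closed-loop 0D circulation model

Coronary hemodynamics is represented with the standard electric-circuit
analogy. Each anatomical branch — a length of artery between bifurcations —
maps to one vessel segment with

* series resistance $R = 128 \mu l / (\pi d^4)$ (Poiseuille),
* series inertance $L = 4 \rho l / (\pi d^2)$,
* a junction capacitance at its distal node from a thin-wall linear
  compliance, $C = 3\pi r^2 l / (2\,(Eh/r))$ with the empirical stiffness
  fit $Eh/r = k_1 e^{k_2 r} + k_3$ ($k_1 = 2\times10^7$, $k_2 = -22.53$,
  $k_3 = 8.65\times10^5$ in CGS), and
* a quadratic stenosis loss $\Delta P = S\,|Q|\,Q$ with
  $S = K_t \rho / (2A_0^2)\,(A_0/A_s - 1)^2$, $A_s = A_0(1-\text{sev})$,
  $K_t = 1.52$.

All three geometry-to-element maps are exposed as overridable callbacks in
`network_config()`; what the pipeline requires of them is only that they are
consistent and monotone in the geometry. Blood is Newtonian with
$\rho = 1.06$ g/cm$^3$ and $\mu = 0.04$ poise (whole-blood viscosity is
sometimes quoted without its time unit; dimensionally it is a dynamic
viscosity, i.e. poise). Walls are
rigid; there is no fluid–structure interaction and no 3D flow solver in
this package — where high-fidelity values are needed they enter through a
surrogate or through user-supplied evaluation tables.

The loop is closed by four time-varying elastance chambers
($P = E(t)(V - V_0)$, with a raised-cosine activation bump between
$E_\min$ and $E_\max$; the shape function is configurable), smoothed-diode
valves, an aortic Windkessel, a pulmonary RCR bed, and a venous return
node. Coronary outlets carry the classic five-element boundary condition
(Ra – Ca – Ramicro – Cim – Rv) in which the intramyocardial capacitor is
referenced to a scaled chamber pressure (LV for LV-perfusing outlets, RV
otherwise). This reproduces the diastolic character of coronary inflow: the
test suite asserts that mean LV-outlet inflow during systole is below its
diastolic value. Hyperemia multiplies Ra, Ramicro and Rv of every coronary
outlet by 0.24 (configurable); applying the factor to the full distal
triplet (rather than only one element) is a documented package choice.

**Closed-loop element values.** The systemic/pulmonary element values and
chamber elastances are *physiologic placeholders*: patient-specific deployments of
this kind of pipeline calibrate a few dozen such parameters against
clinical data that a synthetic package cannot reproduce. `tune_cardiac_function()` provides a
reduced Nelder–Mead point calibration (aortic pressures, stroke volume,
ejection fraction) over a configurable parameter subset.

**Numerics.** The transient solver integrates the full state (segment flows
and node pressures, chamber volumes, boundary capacitor states) with the
generalized trapezoidal rule ($\theta = 0.5$), chord Newton iteration, and
a finite-difference Jacobian that is reused across steps and refreshed
every 40 steps or on slow convergence. Defaults are 5 cycles at 1000
steps/cycle; the final cycle is retained and the cycle-to-cycle change of
mean aortic pressure and outlet flows is reported (a warning is raised
above 1% — with the default venous compliance the loop settles to ~1% at 5
cycles and to $10^{-4}$ by 8). Mass conservation over the retained cycle is
asserted below 0.5% in the tests. A steady resistor-network reduction
(series/parallel tree sweep with a fixed point on the stenosis-linearized
resistance $R + S|Q|$) serves as the fast inner model for calibration; in
the linear limit it agrees with a dense nodal-analysis oracle to machine
precision. Units are CGS internally; mmHg and mL/min appear only at I/O
boundaries.

## 2. Synthetic cohort

`generate_tree()` builds a three-vessel (LAD/LCx via left main, RCA)
binary tree with strictly tapering diameters, one stenosis per main vessel
(default severities 0.60/0.50/0.55 as fractional area reduction — a
moderate-to-severe diseased patient), and outlets placed on an epicardial
shell around an ellipsoidal LV. Defaults give 16 outlets of which 14
perfuse the LV — a dimensionality typical of a right-dominant clinical
coronary tree. `generate_lv()` samples an ellipsoidal myocardial shell (5000 points
by default) with equal voxel volumes and a smooth MBF field around
2.0 mL/min/mL — a typical hyperemic level — with optional regional deficit.
Both generators are pure functions of (configuration, seed).

What the generator does *not* emulate: real segmentation/registration
artifacts, non-ellipsoidal LV geometry, image-derived MBF heterogeneity
beyond smooth modulation, and correlated (rather than i.i.d.) measurement
noise. A green test therefore establishes the correctness and statistical
behavior of the pipeline's machinery, not clinical accuracy on any patient.

## 3. Perfusion territories and flow targets

Each LV point is assigned to the closest LV-perfusing outlet (ties to the
lowest outlet index — deterministic and documented). Distance noise is
drawn independently per (point, outlet) pair as
$d \to d\,(1 + 0.10\,z)$, $z \sim N(0,1)$; the correlation structure of this
noise is not prescribed anywhere, and per-pair independence is the minimal
assumption (configurable). MBF noise multiplies each point's value
by $(1 + 0.20\,z)$. 2500 joint realizations give the target mean $f_{CT}$
and covariance $\Sigma$; the off-diagonal structure comes from boundary
points hopping between adjacent territories. $\Sigma$ is symmetrized and
eigenvalue-clipped at $10^{-12}\,\mathrm{tr}$ (a conditioning safeguard;
the statistic itself does not prescribe one), with optional diagonal jitter available in the likelihood.
Non-LV outlets never receive territories; their resistances stay at the
Murray-law ($d^{2.6}$ conductance) split.

## 4. Bayesian personalization

The likelihood is the multivariate Gaussian of the flow residuals under
$\Sigma$; the prior is uniform on $[0.5\hat r, 2\hat r]$ where $\hat r$
distributes the total LV-distal resistance proportionally to the target
flows. Sampling uses differential-evolution adaptive Metropolis: proposals
$z = x_i + \gamma(\delta, d')\sum_\delta (x_a - x_b) + e$ with
$\gamma = 2.38/\sqrt{2\delta d'}$, $\delta \le 3$ pairs, subspace crossover
with probabilities adapted over $\{0.1,\dots,1\}$ during burn-in from
normalized jump distances, a $\gamma = 1$ jump mode with probability 0.2,
and tiny proposal jitter. These DREAM internals follow the canonical published defaults and are all
exposed in the configuration.

Two constraint choices deserve note. *Rescaling*: at every generation the
proposal's conductances are scaled by one factor so the parallel
combination matches the stage-1 total; we read "total coronary resistance"
as the parallel (conductance-sum) total, the physiologically meaningful
quantity for a set of outlets fed from a common pressure. *Support*: a
rescaled proposal can exit the prior box; such proposals are rejected,
which preserves the target distribution restricted to the constrained
manifold. Burn-in is fixed at 50%; convergence is judged by split
Gelman–Rubin $\hat R \le 1.1$ per component. Chains are reproducible
bit-for-bit given (seed, chain count).

The parameter-recovery fixture (`make_recovery_problem()`) scales the LV
MBF field territory-by-territory so that the *mean* noisy target equals
the flow vector of a known resistance truth $r^\ast$ (two fixed-point
calibration passes absorb the small mean shift that territory noise
induces); the acceptance suite then checks posterior means within 5% of
$r^\ast$ and predictive flows within one predictive standard deviation of
the targets.

## 5. Quantities of interest

TAWSS is implemented as $(1/T)\int_0^T |\tau|\,dt$: published formulations
sometimes omit the $1/T$ or the magnitude, but "time-averaged" implies
both; the adopted convention is flagged here rather than silently assumed,
and matters when values are compared across studies. OSI uses the
magnitude of the vector time-integral in the numerator, consistent with its
$[0, 0.5]$ range (0.5 attained by any zero-mean waveform — an acceptance
target). FFR is the ratio of *cycle-mean* distal to aortic pressure
(configurable; not the instantaneous ratio). At the 0D level, branch wall
shear is the Poiseuille value $32\mu Q/(\pi d^3)$ of the branch flow
waveform, and "minimum TAWSS / maximum OSI within the stenotic region" is
represented by the stenosis-adjacent node's QoI — spatial fields exist only
in real 3D data, which can be ingested via evaluation tables
(`read_hf_table()`).

The high-fidelity surrogate (`hf_surrogate()`) stands in for the 3D solver:
either a lookup table of user-supplied evaluations, or the 0D model plus a
configurable nonlinear distortion. The default `osi_proxy` distortion maps
the stenosis-branch mean flow through a Gaussian bump centered at the
median operating flow, which makes the HF output non-monotone in the LF
predictor and collapses their correlation below 0.7 — reproducing the
weak/sign-flipped correlations reported for oscillatory shear metrics, and
exercising exactly the regime the shared-space method addresses.

## 6. Multi-fidelity estimators

`mfmc_estimate()` implements the two-model control-variate estimator with
$\alpha = \widehat{\mathrm{Cov}}/\widehat{\mathrm{Var}}$ from the pilot
pairs and the analytic variance
$\mathrm{Var}(Q_{HF})/N_{HF}\,(1 - (\Delta/N_{LF})\rho^2)$. All moments use
the unbiased $(N-1)$ convention (the governing formulas are
population-level; the convention is documented because it enters the
variance ratio tests). Estimating $\alpha$ from the same pilot used in the
estimator induces a small $O(1/N)$ bias that is accepted as standard
practice. Chebyshev intervals use half-width $\sigma/\sqrt{1-\text{level}}$
($\sigma\sqrt{20}$ at 95%, $10\sigma$ at 99%) — distribution-free and
conservative, so empirical coverage exceeds the nominal level. The optimal
allocation floors both counts and spends leftover budget on LF samples;
the default cost ratio $w = 1/2500$ mirrors a ~10 s LF versus ~7 h HF
evaluation.

## 7. Shared-space resampling

Each fidelity receives a supervised autoencoder (encoder
$\mathcal E: \mathbb R^d \to \mathbb R$, decoder $\mathcal D$, and a latent
surrogate head $Q_{NN}$) trained on the four-term loss combining surrogate
accuracy, surrogate consistency under reconstruction, and reconstruction
idempotence. There is deliberately no direct input-reconstruction term: the
latent is meant to capture the QoI's active 1D manifold, not the input
distribution. With a 1D latent the normalizing flow is analytic: the
piecewise-linear empirical CDF (plotting positions $(i-0.5)/n$, edge-slope
extrapolation, clipping at $10^{-4}$) composed with the standard normal
quantile function. Stage 2 fine-tunes both autoencoders jointly with a
correlation bonus $-|\rho[Q_{HF}, Q_{NN}^{LF}(T_{LF}^{-1}T_{HF}\mathcal
E_{HF}(\theta))]|$ — the bonus is routed through the LF surrogate head
(cheap to differentiate) rather than the true LF model; the flows are held fixed
between refits and refit every 10 epochs because the latent distribution
moves as the weights train.

Design choices made where the design was genuinely open:

* **No autodiff framework exists in the deployment environment**, so the
  networks (2 hidden layers × 32 tanh units) are trained with hand-written
  backpropagation and full-batch Adam. Gradients are verified against
  finite differences in the test suite.
* **Training hyperparameters**: learning
  rate $3\times10^{-3}$ with cosine decay to a tenth, decoupled weight
  decay $10^{-4}$, up to 3000 stage-1 / 1500 stage-2 epochs with early
  stopping on a 20% validation split. The decay and weight decay were
  adopted because the small-sample regime (pilots of 25–500) otherwise
  overfits; all values sit in `ae_config()`.
* **LF-side training set**: the low-fidelity autoencoder trains on a larger
  LF-only sample (default 1000 extra evaluations) in addition to the pilot
  — low-fidelity evaluations are abundant by construction in this setting.
* **Checkpoint selection**: when the true LF model is available (it always
  is — it is the cheap model), stage-2 checkpoints are scored by the true
  resampled correlation rather than the surrogate loss, and the best
  checkpoint is kept.
* **Orientation**: a 1D shared space is defined only up to reflection;
  the map is canonicalized by reflecting the Gaussian space (which leaves
  its distribution invariant) whenever the resampled correlation on the
  pilot is negative. Reported modified correlations are therefore
  positive, matching how such results are conventionally tabulated.
* **Extrapolation**: inputs beyond the flow support are clipped (clip
  events are counted on the result, not fatal).
* $d_r > 1$ is rejected with a clear message: the analytic flow
  construction is specific to one dimension.

The resampler evaluates the *true* LF model at
$\mathcal D_{LF}(T_{LF}^{-1}(T_{HF}(\mathcal E_{HF}(\theta))))$, and
`mfmc_ae_estimate()` plugs these values into the MFMC form. Unbiasedness
(over independent input draws, for a fixed trained map) follows from the
telescoping control-variate structure and is verified by 200-trial studies.
The correlation-improvement property is exercised on five fixture pairs
spanning $\rho \in \{-0.9, -0.4, 0.1, 0.6, 0.95\}$ built from two monotone
1D projections at controlled angles — both models have exact 1D active
manifolds, the regime the method is designed for, with closed-form true
means for the bias oracles.

## 8. Known limitations

* The closed-loop element defaults are population-plausible placeholders,
  not a calibrated patient; absolute pressures/flows are only
  physiologically *reasonable* (the tests assert structure — conservation,
  monotonicity, convergence — not absolute hemodynamic values).
* The high-fidelity surrogate shares its physics with the low-fidelity
  model up to a synthetic distortion; conclusions about *clinical* 3D/0D
  correlations require real 3D tables plugged in via `read_hf_table()`.
* Stage-2 training maximizes a pilot-sample correlation; with very small
  pilots (≤ 50) the reported $\rho_{AE}$ is optimistic relative to fresh
  draws (the convergence study quantifies the spread).
* The DREAM implementation omits outlier-chain replacement; on the
  well-posed unimodal posteriors exercised here it is unnecessary.
* Sampling distributions of territory statistics assume i.i.d. noise;
  clinically informed correlated noise would change $\Sigma$ and hence the
  posterior spread, though not the machinery.
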