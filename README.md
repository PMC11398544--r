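# coroUQ — personalized, uncertainty-aware coronary hemodynamics

`coroUQ` is an R implementation of an end-to-end pipeline for simulating
coronary artery blood flow with *vessel-specific* personalization and
honest uncertainty quantification. It is aimed at researchers in
cardiovascular modeling who want to (a) calibrate lumped-parameter coronary
models against myocardial-perfusion-derived branch flows, and (b) estimate
clinical and biomechanical quantities of interest (QoIs) with multi-fidelity
Monte Carlo at a fraction of the single-fidelity cost.

## What it does

1. **0D closed-loop circulation model.** Each coronary branch becomes a
   lumped segment with Poiseuille resistance `R = 128 μ l / (π d⁴)`,
   inertance `L = 4 ρ l / (π d²)`, junction compliance, and a quadratic
   stenosis loss `ΔP = S |Q| Q`. Four time-varying elastance chambers
   (`P = E(t)(V − V₀)`), Windkessel systemic/pulmonary beds, and coronary
   outlet boundary conditions with intramyocardial pressure close the loop.
   Hyperemia is modeled by scaling distal coronary resistances by 0.24.
   A fast steady resistor-network surrogate serves as the inner model for
   calibration; an implicit (generalized trapezoidal) transient solver
   produces waveforms.

2. **Perfusion flow targets.** The LV myocardium (a point cloud with a
   myocardial blood flow field, MBF) is tessellated into per-outlet
   territories by nearest-outlet distance; integrating MBF over each
   territory gives branch flow targets `f_CT`. Two noise sources —
   Gaussian distance noise (sd = 10% of the deterministic distance) and
   Gaussian MBF noise (sd = 20%) — are propagated through 2500 joint
   realizations to give the target covariance Σ (non-diagonal: adjacent
   territories exchange points).

3. **Bayesian personalization.** The posterior
   `p(r | f_CT) ∝ exp(−½ (f_CT − f(r))ᵀ Σ⁻¹ (f_CT − f(r))) · p(r)` over the
   distal resistances of the LV-perfusing outlets, with a uniform prior on
   `[0.5 r̂, 2 r̂]`, is sampled with a DREAM-style differential-evolution
   adaptive Metropolis sampler (parallel chains, subspace crossover, 50%
   burn-in, split Gelman–Rubin R̂ ≤ 1.1 as the convergence criterion). At
   every generation the components of `r` are rescaled so the total
   (parallel) coronary resistance is preserved.

4. **QoIs.** Time-averaged wall shear stress `TAWSS = (1/T)∫|τ|dt`,
   oscillatory shear index `OSI = ½(1 − |∫τ dt| / ∫|τ| dt) ∈ [0, 0.5]`,
   fractional flow reserve (cycle-mean distal / aortic pressure under
   hyperemia), and mean branch flows. Inputs `θ = (r, s)` combine posterior
   resistance draws with a total-resistance scale `s ~ U(0.7, 1.25)`.

5. **Multi-fidelity estimation.** The MFMC control-variate estimator
   `Q̂ = mean(Q_HF) + α(mean(Q_LF, all) − mean(Q_LF, pilot))`,
   `α = Cov/Var`, with analytic variance
   `Var(Q_HF)/N_HF · (1 − (Δ/N_LF) ρ²)`, Chebyshev 95/99% intervals, and
   the optimal budget allocation `γ = √(ρ² / (w(1 − ρ²)))`.

6. **Shared-space resampling (MFMC-AE).** When the low/high-fidelity
   correlation ρ is weak, each fidelity gets a supervised autoencoder whose
   1D latent captures the QoI's active manifold; analytic normalizing flows
   (empirical CDF → U(0,1) → N(0,1)) link the two latents through a shared
   Gaussian space, and the low-fidelity model is re-evaluated at the
   decoded, shared-space-matched inputs:
   `Q_AE(θ_HF) = Q_LF(D_LF(T_LF⁻¹(T_HF(E_HF(θ_HF)))))`.
   This raises |ρ| — on the bundled fixture pairs from as low as 0.05 to
   above 0.9 — and shrinks the MFMC variance accordingly.

## Worked example

```r
library(coroUQ)

# synthetic 14-LV-outlet personalization problem: hyperemic tree, LV cloud
# with an MBF field generated from a known resistance truth r*, and noisy
# flow targets (10% distance noise, 20% MBF noise, 2500 realizations)
prob <- make_recovery_problem(seed = 1, n_outlets = 16, n_lv = 14,
                              n_points = 5000, n_realizations = 2500)

post <- dream_sample(function(r) flow_loglik(r, prob$targets, prob$model),
                     prob$prior, n_chains = 24, n_generations = 4000,
                     seed = 2)
post
#> <posterior_samples> 24 chains x 4000 generations (burn-in 50%); acceptance 24.4%; max split R-hat 1.047

draws <- posterior_draws(post, thin = 10)
max(abs(colMeans(draws) - prob$r_star) / prob$r_star)
#> [1] 0.0108
```

The printed `max split R-hat 1.047` is below the 1.1 convergence threshold
(all 14 resistance posteriors have mixed), and the posterior means recover
the generating resistances to ~1%. Continuing to the multi-fidelity stage
on a weakly correlated fixture pair:

```r
pair <- fixture_pair(0.1)                  # weak LF/HF correlation by design
map  <- train_shared_space(pair, n_pilot = 300, seed = 5)
map
#> <shared_space_map> rho 0.06844 -> rho_AE 0.8743
X  <- with_seed(6, pair$sample_inputs(40));  hf <- pair$hf_fun(X)
Xe <- with_seed(7, pair$sample_inputs(800))
mfmc_ae_estimate(map, X, hf, Xe)
#> <estimator_result> MFMC-AE: mean 0.804874, sd 0.06019, rho 0.9765 (N3D=40, N0D=840)
mc_estimate(hf)
#> <estimator_result> MC: mean 0.842688, sd 0.1986 (N3D=40, N0D=0)
```

The resampled low-fidelity model raises the correlation from 0.07 to 0.87
on the pilot (0.98 on this estimation draw), and the MFMC-AE standard
deviation (0.060) is ~3x smaller than plain Monte Carlo (0.199) at the
same 40 high-fidelity evaluations: the 95% Chebyshev interval shrinks from
+-0.89 to +-0.27, both covering the exact mean (1) of this fixture. This
is the same mechanism that yields the large confidence-interval reductions
for oscillatory shear metrics in full 3D/0D model pairs.

An end-to-end smoke run (fixtures → targets → posterior → estimators):

```r
run <- run_pipeline(pipeline_config(seed = 1))
report(run)
```

## Layout

- `R/` — circuit construction and solvers, synthetic cohort, perfusion
  targets, DREAM personalization, QoIs, estimators, shared-space
  autoencoders/flows, pipeline.
- `tests/testthat/` — unit + property tests per module and
  `test-acceptance.R` with the acceptance criteria.
- `vignettes/corouq-methods.Rmd` — the model, assumptions, numerical
  choices, and limitations.
- `inst/cli.R` — command-line subcommands (`fixtures`, `targets`,
  `personalize`, `estimate`, `run`, `report`).
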