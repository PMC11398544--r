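# Analytic model pairs and the synthetic personalization problem.
#
# The fixture pairs are deterministic functions of a 6D standard-normal
# input whose low/high-fidelity outputs are driven by two 1D projections at
# a controlled angle, giving a tunable output correlation while both models
# retain exact 1D active manifolds - the regime the shared-space resampler
# is designed for. True means are available in closed form, so estimator
# unbiasedness can be checked against an independent oracle.

#' Analytic low/high-fidelity fixture pair with controlled correlation
#'
#' Q_hf(theta) = 1 + t + 0.25 t^3 with t = w'theta, and
#' Q_lf(theta) = 0.5 + 0.8 u + 0.2 u^3 with u = v'theta, where w, v are
#' unit vectors with w'v = `rho_target` and theta ~ N(0, I_d). Both outputs
#' are monotone along their own 1D projection; the achieved output
#' correlation is close to (and reported with) the projection correlation.
#' The exact high-fidelity mean is 1 (odd terms vanish under the standard
#' normal).
#'
#' @param rho_target projection correlation w'v in (-1, 1).
#' @param d input dimension (>= 2).
#' @return List with `hf_fun`, `lf_fun` (vectorized over input rows),
#'   `sample_inputs(n)` (draws from the caller's RNG stream), `true_mean`
#'   (HF), `rho_target`, `d`.
#' @export
fixture_pair <- function(rho_target, d = 6) {
  stopifnot(abs(rho_target) < 1, d >= 2)
  w <- rep(1, d) / sqrt(d)
  w_perp <- rep(c(1, -1), length.out = d)
  w_perp <- w_perp - sum(w_perp * w) * w
  w_perp <- w_perp / sqrt(sum(w_perp^2))
  v <- rho_target * w + sqrt(1 - rho_target^2) * w_perp
  g <- function(t) 1 + t + 0.25 * t^3
  h <- function(u) 0.5 + 0.8 * u + 0.2 * u^3
  list(
    hf_fun = function(X) g(drop(as.matrix(X) %*% w)),
    lf_fun = function(X) h(drop(as.matrix(X) %*% v)),
    sample_inputs = function(n) matrix(stats::rnorm(n * d), n, d),
    true_mean = 1,
    rho_target = rho_target,
    d = d
  )
}

#' Synthetic coronary personalization problem with known truth
#'
#' Builds the full fixture for parameter-recovery studies: a coronary tree
#' with `n_lv` LV-perfusing outlets under hyperemia, an LV point cloud whose
#' MBF field is scaled territory-by-territory so that the deterministic
#' branch flows equal the flows produced by a known resistance vector
#' r_star, and uncertainty-aware flow targets built from the stated noise
#' model (10% distance noise, 20% MBF noise). The posterior over outlet
#' resistances should then concentrate near r_star.
#'
#' @param seed integer master seed.
#' @param n_outlets,n_lv tree outlet counts (see [generate_tree()]).
#' @param n_points LV point-cloud size.
#' @param n_realizations noise realizations for the target statistics.
#' @param distance_noise,mbf_noise noise fractions.
#' @param r_spread lognormal spread of r_star around the Murray-law
#'   reference (before rescaling to the total).
#' @return List with `net` (hyperemic `circuit_network`), `lv`, `outlets`,
#'   `targets` (`flow_target_set`), `r_star`, `total_resistance`,
#'   `model` (function(r) -> LV outlet flows, mL/min), `prior`
#'   ([prior_spec()] built from the target flows).
#' @export
make_recovery_problem <- function(seed = 1, n_outlets = 16, n_lv = 14,
                                  n_points = 5000, n_realizations = 2500,
                                  distance_noise = 0.10, mbf_noise = 0.20,
                                  r_spread = 0.15) {
  tree <- generate_tree(n_outlets = n_outlets, seed = seed, n_lv = n_lv)
  net <- apply_hyperemia(build_network(tree))
  outlets <- outlet_set(tree)
  lv <- generate_lv(n_points = n_points, seed = seed + 1)

  # known truth: lognormal perturbation of the Murray-law reference,
  # projected onto the total-resistance constraint
  r_hat0 <- outlet_resistances_lv(net)
  total_R <- 1 / sum(1 / r_hat0)
  r_star <- with_seed(seed + 2, {
    rescale_preserve_total(
      r_hat0 * exp(stats::rnorm(length(r_hat0), 0, r_spread)), total_R)
  })
  f_star <- lv_outlet_flows(net, r_star)   # mL/min

  # rescale the MBF field per deterministic territory so the branch flows
  # reproduce f_star; two further passes correct the small mean shift that
  # territory (distance) noise induces, so that the *mean* target equals
  # f(r_star) and the posterior truth is well defined
  assign0 <- assign_territories(lv, outlets, distance_noise = 0)
  f_det <- branch_flows(lv, assign0, mbf_noise = 0)
  lv$mbf <- lv$mbf * (f_star / f_det)[assign0$index]
  for (pass in 1:2) {
    cal <- build_flow_targets(lv, outlets,
                              n_realizations = min(500, n_realizations),
                              distance_noise = distance_noise,
                              mbf_noise = mbf_noise, seed = seed + 20 + pass,
                              keep_realizations = FALSE)
    lv$mbf <- lv$mbf * (f_star / cal$mean)[assign0$index]
  }

  targets <- build_flow_targets(lv, outlets, n_realizations = n_realizations,
                                distance_noise = distance_noise,
                                mbf_noise = mbf_noise, seed = seed + 3)
  model <- function(r) lv_outlet_flows(net, r)
  prior <- prior_spec(reference_resistances(total_R, targets$mean))
  list(net = net, tree = tree, lv = lv, outlets = outlets, targets = targets,
       r_star = r_star, total_resistance = total_R, f_star = f_star,
       model = model, prior = prior, seed = seed)
}
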