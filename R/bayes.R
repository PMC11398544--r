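# Bayesian personalization of coronary outlet resistances.
#
# Posterior p(r | f_CT) over the distal resistances of the LV-perfusing
# outlets, with a Gaussian likelihood on the branch-flow residuals
# (covariance from the noisy-perfusion realizations) and a uniform prior
# [0.5 r_hat, 2 r_hat]. Sampling uses a differential-evolution adaptive
# Metropolis (DREAM) scheme with subspace crossover; at every generation the
# components of r are rescaled so the total (parallel) coronary resistance
# is preserved.

#' Uniform prior specification over outlet resistances
#'
#' @param r_hat reference resistances (componentwise positive), typically
#'   from [reference_resistances()].
#' @param lower,upper box factors: support is [lower * r_hat, upper * r_hat].
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(r_hat, lower = 0.5, upper = 2.0) {
  stopifnot(all(r_hat > 0), lower < upper, lower > 0)
  structure(list(r_hat = r_hat, lower = lower, upper = upper,
                 total_resistance = 1 / sum(1 / r_hat)),
            class = "prior_spec")
}

#' Reference resistances from relative target flows
#'
#' Distributes a total (parallel) resistance among outlets so that outlet
#' conductances are proportional to the target flows: the outlets then draw
#' the target flow split when fed from a common pressure.
#'
#' @param total_resistance total resistance distal to the LV-perfusing
#'   arteries (parallel combination of the result), > 0.
#' @param target_flows positive flow targets (any consistent unit).
#' @return Vector r_hat with 1/sum(1/r_hat) = total_resistance.
#' @export
reference_resistances <- function(total_resistance, target_flows) {
  if (any(target_flows <= 0)) stop("target flows must be positive")
  stopifnot(total_resistance > 0)
  g <- target_flows / sum(target_flows) / total_resistance
  stats::setNames(1 / g, names(target_flows))
}

#' Rescale resistances to preserve the total coronary resistance
#'
#' Multiplies all conductances by one scalar so the parallel combination
#' equals `total_resistance`; the ratios r_i / r_j (hence the flow splits)
#' are unchanged.
#'
#' @param r positive resistance vector.
#' @param total_resistance target parallel total.
#' @return Rescaled vector.
#' @export
rescale_preserve_total <- function(r, total_resistance) {
  stopifnot(all(r > 0), total_resistance > 0)
  lambda <- (1 / total_resistance) / sum(1 / r)
  r / lambda
}

#' Gaussian log-likelihood of flow targets
#'
#' log p(f_CT | r) = -1/2 (f_CT - f(r))' Sigma^-1 (f_CT - f(r))
#'                  - 1/2 log((2 pi)^Nc det Sigma),
#' where f(r) is the model's simulated outflow vector.
#'
#' @param r resistance vector.
#' @param targets a `flow_target_set` (Sigma must be invertible after
#'   repair; a tiny diagonal `jitter` relative to the mean diagonal can be
#'   added for conditioning).
#' @param model function(r) returning the simulated flows (length Nc, same
#'   units as the targets).
#' @param jitter relative diagonal jitter.
#' @return Scalar log-likelihood; -Inf (with attribute "diagnostic") if the
#'   model output is non-finite.
#' @export
flow_loglik <- function(r, targets, model, jitter = 0) {
  f <- model(r)
  if (!all(is.finite(f))) {
    out <- -Inf
    attr(out, "diagnostic") <- "non-finite model output"
    return(out)
  }
  ll_gauss(unname(targets$mean) - unname(f), sigma_chol(targets, jitter))
}

sigma_chol <- function(targets, jitter = 0) {
  S <- unname(targets$sigma)
  if (jitter > 0) S <- S + diag(jitter * mean(diag(S)), nrow(S))
  chol(S)
}

ll_gauss <- function(resid, R) {
  # R = chol(Sigma), upper triangular
  z <- backsolve(R, resid, transpose = TRUE)
  -0.5 * sum(z^2) - 0.5 * (length(resid) * log(2 * pi)) - sum(log(diag(R)))
}

#' DREAM-style adaptive MCMC over outlet resistances
#'
#' Differential-evolution Metropolis with subspace crossover: the proposal
#' for chain i is z = x_i + gamma(delta, d') sum_{j=1..delta}(x_aj - x_bj)
#' + e, where gamma = 2.38 / sqrt(2 delta d') (replaced by 1 with
#' probability `jump_prob` to enable mode jumps), d' is the number of
#' dimensions selected by the crossover mask, and e is a tiny Gaussian
#' jitter. Crossover probabilities over {1/nCR, ..., 1} are adapted during
#' burn-in from normalized jump distances. Every proposal is rescaled to the
#' total-resistance constraint before evaluation; proposals leaving the
#' prior box after rescaling are rejected, which preserves the target on the
#' constrained manifold.
#'
#' @param log_lik function(r) -> scalar log-likelihood.
#' @param prior a [prior_spec()].
#' @param n_chains number of parallel chains (a warning is issued below
#'   2 x dimension).
#' @param n_generations generations per chain.
#' @param seed integer seed (chains are reproducible bit-for-bit).
#' @param burn_in fraction of generations discarded as burn-in.
#' @param delta_max maximum number of difference pairs.
#' @param jump_prob probability of a gamma = 1 jump.
#' @param nCR number of crossover levels.
#' @param jitter proposal jitter standard deviation (absolute, applied on
#'   the unit-scaled parameters).
#' @param stagnation_window,stagnation_rate all-chain stagnation diagnostic:
#'   error if acceptance < `stagnation_rate` over the last
#'   `stagnation_window` generations.
#' @param preserve_total apply the total-resistance rescaling at every
#'   generation (the personalization setting). FALSE samples the
#'   unconstrained box prior, which is useful for validation against
#'   closed-form posteriors.
#' @return Object of class `posterior_samples`: `chains` (array
#'   generations x chains x dim, post-rescaling), `log_post`, `burn_in`,
#'   `gelman_rubin` (split R-hat per component, post burn-in),
#'   `acceptance_rate`, `prior`, `seed`.
#' @export
dream_sample <- function(log_lik, prior, n_chains = 24, n_generations = 10000,
                         seed = 1, burn_in = 0.5, delta_max = 3,
                         jump_prob = 0.2, nCR = 10, jitter = 1e-6,
                         stagnation_window = 500, stagnation_rate = 0.01,
                         preserve_total = TRUE) {
  stopifnot(inherits(prior, "prior_spec"), n_chains >= 3, n_generations >= 10)
  d <- length(prior$r_hat)
  if (n_chains < 2 * d)
    warning("n_chains < 2 x dimension (", n_chains, " < ", 2 * d,
            "); mixing may be slow")
  lo <- prior$lower * prior$r_hat
  hi <- prior$upper * prior$r_hat
  Rtot <- prior$total_resistance
  scale_r <- prior$r_hat   # unit scaling for jitter / jump distances

  with_seed(seed, {
    # initial population: uniform on the box, projected to the constraint
    X <- matrix(NA_real_, n_chains, d)
    lp <- numeric(n_chains)
    for (i in seq_len(n_chains)) {
      for (try in 1:1000) {
        z <- stats::runif(d, lo, hi)
        if (preserve_total) z <- rescale_preserve_total(z, Rtot)
        if (all(z >= lo) && all(z <= hi)) break
      }
      if (any(z < lo) || any(z > hi))
        stop("could not initialize chain inside the constrained prior")
      X[i, ] <- z
      lp[i] <- log_lik(z)
    }

    CRvals <- seq_len(nCR) / nCR
    pCR <- rep(1 / nCR, nCR)
    JCR <- rep(0, nCR); nCRuse <- rep(0, nCR)

    chains <- array(NA_real_, c(n_generations, n_chains, d))
    logp <- matrix(NA_real_, n_generations, n_chains)
    n_acc <- 0; acc_recent <- integer(0)
    burn_gen <- floor(burn_in * n_generations)

    for (g in seq_len(n_generations)) {
      acc_this <- 0
      dmax <- min(delta_max, (n_chains - 1) %/% 2)
      for (i in seq_len(n_chains)) {
        delta <- sample.int(dmax, 1)
        others <- sample(setdiff(seq_len(n_chains), i), 2 * delta)
        a <- others[seq_len(delta)]; b <- others[delta + seq_len(delta)]
        diffv <- colSums(X[a, , drop = FALSE]) - colSums(X[b, , drop = FALSE])

        m <- sample.int(nCR, 1, prob = pCR)
        mask <- stats::runif(d) < CRvals[m]
        if (!any(mask)) mask[sample.int(d, 1)] <- TRUE
        dprime <- sum(mask)
        gamma <- if (stats::runif(1) < jump_prob) 1 else
          2.38 / sqrt(2 * delta * dprime)

        z <- X[i, ]
        z[mask] <- z[mask] + gamma * diffv[mask] +
          jitter * scale_r[mask] * stats::rnorm(dprime)
        ok <- all(z > 0)
        if (ok) {
          if (preserve_total) z <- rescale_preserve_total(z, Rtot)
          ok <- all(z >= lo) && all(z <= hi)
        }
        if (ok) {
          lpz <- log_lik(z)
          if (is.finite(lpz) || is.finite(lp[i])) {
            if (log(stats::runif(1)) < lpz - lp[i]) {
              if (g <= burn_gen) {
                jd <- sum(((z - X[i, ]) / scale_r)^2)
                JCR[m] <- JCR[m] + jd
              }
              X[i, ] <- z; lp[i] <- lpz
              acc_this <- acc_this + 1
            }
          }
        }
        if (g <= burn_gen) nCRuse[m] <- nCRuse[m] + 1
      }
      chains[g, , ] <- X
      logp[g, ] <- lp
      n_acc <- n_acc + acc_this
      acc_recent <- c(acc_recent, acc_this)
      if (length(acc_recent) > stagnation_window)
        acc_recent <- acc_recent[-1]
      if (g %% stagnation_window == 0 &&
          sum(acc_recent) / (stagnation_window * n_chains) < stagnation_rate)
        stop("all-chain stagnation: acceptance < ",
             100 * stagnation_rate, "% over the last ",
             stagnation_window, " generations")
      # adapt crossover probabilities during burn-in
      if (g <= burn_gen && g %% 50 == 0 && all(nCRuse > 0)) {
        w <- JCR / nCRuse
        if (sum(w) > 0) pCR <- 0.1 / nCR + 0.9 * w / sum(w)
      }
    }

    post <- chains[(burn_gen + 1):n_generations, , , drop = FALSE]
    rhat <- gelman_rubin(post)
    structure(list(chains = chains, log_post = logp,
                   burn_in = burn_in, burn_gen = burn_gen,
                   gelman_rubin = rhat,
                   acceptance_rate = n_acc / (n_generations * n_chains),
                   prior = prior, seed = seed,
                   n_chains = n_chains, n_generations = n_generations),
              class = "posterior_samples")
  })
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("<posterior_samples> ", x$n_chains, " chains x ", x$n_generations,
      " generations (burn-in ", 100 * x$burn_in, "%); acceptance ",
      signif(100 * x$acceptance_rate, 3), "%; max split R-hat ",
      signif(max(x$gelman_rubin), 4), "\n", sep = "")
  invisible(x)
}

#' Post-burn-in draws as a matrix
#'
#' @param samples a `posterior_samples`.
#' @param thin keep every `thin`-th generation.
#' @return Matrix (draws x dim).
#' @export
posterior_draws <- function(samples, thin = 1) {
  gens <- seq(samples$burn_gen + 1, samples$n_generations, by = thin)
  post <- samples$chains[gens, , , drop = FALSE]
  d <- dim(post)[3]
  matrix(aperm(post, c(2, 1, 3)), ncol = d)
}

#' Split Gelman-Rubin convergence diagnostic
#'
#' Each chain's retained samples are split in half; R-hat is the standard
#' between/within variance ratio over the resulting 2m sequences,
#' sqrt(((n-1)/n W + B/n) / W), per component.
#'
#' @param chains array (generations x chains x dim), or (generations x
#'   chains) for a single component.
#' @return Vector of R-hat values (length dim).
#' @export
gelman_rubin <- function(chains) {
  if (length(dim(chains)) == 2) dim(chains) <- c(dim(chains), 1)
  ng <- dim(chains)[1]; m <- dim(chains)[2]; d <- dim(chains)[3]
  if (m < 2) stop("gelman_rubin requires at least 2 chains")
  half <- floor(ng / 2)
  if (half < 5) stop("need at least 10 retained samples per chain")
  vapply(seq_len(d), function(j) {
    seqs <- c(lapply(seq_len(m), function(i) chains[1:half, i, j]),
              lapply(seq_len(m), function(i) chains[(ng - half + 1):ng, i, j]))
    n <- half
    means <- vapply(seqs, mean, 0)
    vars <- vapply(seqs, stats::var, 0)
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, 0)
}

#' Posterior predictive flow distributions
#'
#' Evaluates the flow model on a thinned set of posterior draws and returns
#' per-outlet summaries.
#'
#' @param samples a `posterior_samples`.
#' @param model function(r) -> flow vector.
#' @param thin thinning interval for predictive evaluation.
#' @param probs quantiles to report.
#' @return List with `flows` (draws x outlets matrix), `mean`, `sd`,
#'   `quantiles`, `covariance`.
#' @export
posterior_predictive_flows <- function(samples, model, thin = 10,
                                       probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  R <- posterior_draws(samples, thin = thin)
  flows <- t(apply(R, 1, model))
  list(flows = flows,
       mean = colMeans(flows),
       sd = apply(flows, 2, stats::sd),
       quantiles = apply(flows, 2, stats::quantile, probs = probs),
       covariance = stats::cov(flows))
}

#' Reduced cardiac-function tuner
#'
#' Derivative-free (Nelder-Mead) point calibration of a small set of
#' systemic parameters so the closed-loop model matches systolic/diastolic
#' aortic pressure, stroke volume, and ejection fraction targets. This is a
#' reduced stand-in for a full 36-parameter systemic calibration, which
#' requires patient data outside this package's scope; the tunable subset is
#' configurable.
#'
#' @param net a `circuit_network`.
#' @param targets named list: `sbp`, `dbp` (mmHg), `stroke_volume` (mL),
#'   `ef` (fraction).
#' @param params character subset of
#'   c("lv_emax", "systemic_resistance", "systemic_compliance") to tune
#'   (as multiplicative factors on the current values).
#' @param n_cycles,steps_per_cycle simulation resolution for each objective
#'   evaluation (coarser than production defaults for tractability).
#' @param maxit Nelder-Mead iteration cap.
#' @return List with `net` (tuned network), `factors`, `metrics` (achieved
#'   sbp/dbp/stroke volume/ef), `value` (final objective), `convergence`.
#' @export
tune_cardiac_function <- function(net,
                                  targets = list(sbp = 120, dbp = 80,
                                                 stroke_volume = 75, ef = 0.6),
                                  params = c("lv_emax", "systemic_resistance"),
                                  n_cycles = 3, steps_per_cycle = 400,
                                  maxit = 40) {
  apply_factors <- function(net, f) {
    if (!is.na(f["lv_emax"])) {
      ch <- net$chambers$LV
      ch$elastance_max <- ch$elastance_max * exp(f[["lv_emax"]])
      net$chambers$LV <- ch
    }
    if (!is.na(f["systemic_resistance"])) {
      s <- exp(f[["systemic_resistance"]])
      net$aortic_bc$Rp <- net$aortic_bc$Rp * s
      net$aortic_bc$Rd <- net$aortic_bc$Rd * s
    }
    if (!is.na(f["systemic_compliance"]))
      net$aortic_bc$C <- net$aortic_bc$C * exp(f[["systemic_compliance"]])
    net
  }
  metrics <- function(res) {
    pao <- dyncm2_to_mmHg(res$pressures[, "aorta"])
    vlv <- res$chamber_volumes[, "LV"]
    sv <- max(vlv) - min(vlv)
    list(sbp = max(pao), dbp = min(pao), stroke_volume = sv,
         ef = sv / max(vlv))
  }
  obj <- function(x) {
    f <- stats::setNames(rep(NA_real_, 3),
                         c("lv_emax", "systemic_resistance",
                           "systemic_compliance"))
    f[params] <- x
    res <- tryCatch(
      suppressWarnings(simulate_zerod(apply_factors(net, f),
                                      n_cycles = n_cycles,
                                      steps_per_cycle = steps_per_cycle)),
      error = function(e) NULL)
    if (is.null(res)) return(1e6)
    m <- metrics(res)
    sum(vapply(names(targets), function(k)
      ((m[[k]] - targets[[k]]) / targets[[k]])^2, 0))
  }
  opt <- stats::optim(rep(0, length(params)), obj, method = "Nelder-Mead",
                      control = list(maxit = maxit))
  f <- stats::setNames(rep(NA_real_, 3),
                       c("lv_emax", "systemic_resistance",
                         "systemic_compliance"))
  f[params] <- opt$par
  tuned <- apply_factors(net, f)
  res <- suppressWarnings(simulate_zerod(tuned, n_cycles = n_cycles,
                                         steps_per_cycle = steps_per_cycle))
  list(net = tuned, factors = exp(opt$par)[seq_along(params)],
       metrics = metrics(res), value = opt$value,
       convergence = opt$convergence)
}
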