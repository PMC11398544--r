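# Monte Carlo and multi-fidelity Monte Carlo estimation.
#
# The MFMC estimator combines N3D high-fidelity evaluations with
# N0D = N3D + Delta0D low-fidelity evaluations as a control variate:
#   Qhat = mean(Q3D) + alpha (mean of all Q0D - mean of Q0D at pilot inputs)
# with alpha = Cov(Q3D, Q0D) / Var(Q0D), giving the analytic variance
#   Var[Qhat] = Var(Q3D)/N3D (1 - (Delta0D/N0D) rho^2).
# All moment estimates use the unbiased (N-1) sample convention.

#' Paired low/high-fidelity sample set
#'
#' @param hf_values high-fidelity QoI values at the N3D pilot inputs.
#' @param lf_at_hf low-fidelity values at the same pilot inputs
#'   (index-aligned with `hf_values`).
#' @param lf_extra low-fidelity values at the Delta0D additional,
#'   independently drawn inputs.
#' @return Object of class `sample_pair_set`.
#' @export
sample_pair_set <- function(hf_values, lf_at_hf, lf_extra = numeric(0)) {
  stopifnot(length(hf_values) == length(lf_at_hf))
  structure(list(hf = as.numeric(hf_values), lf = as.numeric(lf_at_hf),
                 lf_extra = as.numeric(lf_extra),
                 N3D = length(hf_values),
                 N0D = length(hf_values) + length(lf_extra)),
            class = "sample_pair_set")
}

new_estimator_result <- function(estimator, mean, variance, n3d, n0d,
                                 rho = NA_real_, alpha = NA_real_) {
  structure(list(estimator = estimator, mean = mean, variance = variance,
                 rho = rho, alpha = alpha, N3D = n3d, N0D = n0d,
                 ci95 = chebyshev_bounds(mean, variance, 0.95),
                 ci99 = chebyshev_bounds(mean, variance, 0.99)),
            class = "estimator_result")
}

#' @export
print.estimator_result <- function(x, ...) {
  cat("<estimator_result> ", x$estimator, ": mean ", signif(x$mean, 6),
      ", sd ", signif(sqrt(x$variance), 4),
      if (!is.na(x$rho)) paste0(", rho ", signif(x$rho, 4)) else "",
      " (N3D=", x$N3D, ", N0D=", x$N0D, ")\n", sep = "")
  invisible(x)
}

#' Standard Monte Carlo estimate of a mean
#'
#' @param values QoI sample values (N >= 2).
#' @return An `estimator_result` with `variance` = sample variance / N.
#' @export
mc_estimate <- function(values) {
  if (length(values) < 2) stop("mc_estimate requires N >= 2")
  n <- length(values)
  new_estimator_result("MC", mean(values), stats::var(values) / n, n, 0)
}

#' Optimal control-variate coefficient
#'
#' alpha = Cov(Q3D, Q0D) / Var(Q0D), estimated from the paired pilot
#' samples.
#'
#' @param pairs a [sample_pair_set()].
#' @return Scalar alpha.
#' @export
control_coefficient <- function(pairs) {
  v <- stats::var(pairs$lf)
  if (v <= 0) stop("zero low-fidelity variance")
  stats::cov(pairs$hf, pairs$lf) / v
}

#' Multi-fidelity Monte Carlo estimate
#'
#' @param pairs a [sample_pair_set()].
#' @param alpha optional fixed control coefficient (default: estimated from
#'   the pilot pairs; `alpha = 0` reduces to plain MC on the HF values).
#' @param label estimator label for reporting.
#' @return An `estimator_result` with the analytic variance
#'   Var(Q3D)/N3D (1 - (Delta0D/N0D) rho^2).
#' @export
mfmc_estimate <- function(pairs, alpha = NULL, label = "MFMC") {
  stopifnot(inherits(pairs, "sample_pair_set"))
  alpha <- alpha %||% control_coefficient(pairs)
  lf_all <- c(pairs$lf, pairs$lf_extra)
  est <- mean(pairs$hf) + alpha * (mean(lf_all) - mean(pairs$lf))
  rho <- if (stats::sd(pairs$lf) > 0 && stats::sd(pairs$hf) > 0)
    stats::cor(pairs$hf, pairs$lf) else 0
  delta <- pairs$N0D - pairs$N3D
  vr <- stats::var(pairs$hf) / pairs$N3D *
    (1 - delta / pairs$N0D * rho^2)
  new_estimator_result(label, est, vr, pairs$N3D, pairs$N0D, rho, alpha)
}

#' Optimal budget allocation for MFMC
#'
#' For budget B (in high-fidelity-equivalent cost units) and cost ratio
#' w = cost(LF)/cost(HF): gamma = sqrt(rho^2 / (w (1 - rho^2))),
#' N3D = B / (1 + w gamma), N0D = gamma N3D; counts are floored (N3D >= 1)
#' and leftover budget is spent on additional LF samples.
#'
#' @param B budget, >= 1.
#' @param w cost ratio in (0, 1); the default mirrors a ~10 s low-fidelity
#'   vs ~7 h high-fidelity evaluation.
#' @param rho low/high-fidelity Pearson correlation (|rho| < 1).
#' @return Object of class `allocation_plan`: list(B, w, gamma, N3D, N0D,
#'   cost).
#' @export
optimal_allocation <- function(B, w = 1 / 2500, rho) {
  stopifnot(B >= 1, w > 0, w < 1)
  if (rho^2 >= 1) stop("|rho| = 1: unbounded LF-to-HF ratio")
  gamma <- sqrt(rho^2 / (w * (1 - rho^2)))
  if (gamma == 0) {
    n3 <- floor(B); n0 <- 0
  } else {
    n3 <- max(1, floor(B / (1 + w * gamma)))
    n0 <- floor(gamma * n3)
    n0 <- n0 + max(0, floor((B - n3 - w * n0) / w))   # leftover to LF
    n0 <- max(n0, n3)
  }
  structure(list(B = B, w = w, gamma = gamma, N3D = n3, N0D = n0,
                 cost = n3 + w * n0),
            class = "allocation_plan")
}

chebyshev_bounds <- function(mean, variance, level) {
  half <- sqrt(variance) / sqrt(1 - level)
  c(lower = mean - half, upper = mean + half)
}

#' Chebyshev confidence interval of an estimator result
#'
#' Distribution-free interval with half-width sd / sqrt(1 - level)
#' (sd * sqrt(20) at 95%, sd * 10 at 99%).
#'
#' @param result an `estimator_result`.
#' @param level confidence level in (0, 1).
#' @return Named vector c(lower, upper).
#' @export
chebyshev_interval <- function(result, level = 0.95) {
  stopifnot(level > 0, level < 1)
  chebyshev_bounds(result$mean, result$variance, level)
}

#' Empirical bias/variance trial study of an estimator
#'
#' Repeats an estimator construction on independent input draws and compares
#' the empirical variance of the trial means with the (mean) analytic
#' variance.
#'
#' @param make_trial function(trial_index) returning an `estimator_result`
#'   for a fresh, independent input draw.
#' @param n_trials number of independent trials (>= 2).
#' @param seed integer seed (the whole study is reproducible).
#' @param true_mean optional known true mean for bias assessment.
#' @return List with `means`, `empirical_mean`, `empirical_variance`,
#'   `analytic_variance` (mean over trials), `variance_ratio`
#'   (empirical/analytic), and - when `true_mean` is given - `bias`,
#'   `bias_se` (standard error of the empirical mean) and `bias_z`.
#' @export
estimator_trial_study <- function(make_trial, n_trials = 200, seed = 1,
                                  true_mean = NULL) {
  stopifnot(n_trials >= 2)
  with_seed(seed, {
    res <- lapply(seq_len(n_trials), make_trial)
    means <- vapply(res, function(r) r$mean, 0)
    avar <- mean(vapply(res, function(r) r$variance, 0))
    out <- list(means = means,
                empirical_mean = mean(means),
                empirical_variance = stats::var(means),
                analytic_variance = avar,
                variance_ratio = stats::var(means) / avar)
    if (!is.null(true_mean)) {
      se <- stats::sd(means) / sqrt(n_trials)
      out$bias <- mean(means) - true_mean
      out$bias_se <- se
      out$bias_z <- out$bias / se
    }
    out
  })
}

#' Serialize an estimator result to JSON
#'
#' @param result an `estimator_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_estimator_report <- function(result, path) {
  obj <- list(schema_version = 1L, estimator = result$estimator,
              mean = result$mean, variance = result$variance,
              rho = result$rho, alpha = result$alpha,
              ci95 = unname(result$ci95), ci99 = unname(result$ci99),
              N3D = result$N3D, N0D = result$N0D)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
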