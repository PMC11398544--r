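# Bayesian personalization: reference splits, likelihood, DREAM sampler,
# convergence diagnostics.

test_that("reference_resistances distributes conductance by flow", {
  expect_equal(unname(reference_resistances(500, c(1, 1))), c(1000, 1000))
  r <- reference_resistances(300, c(3, 1))
  expect_equal(r[[1]] / r[[2]], 1 / 3, tolerance = 1e-12)
  expect_equal(1 / sum(1 / r), 300, tolerance = 1e-12)
  expect_equal(unname(reference_resistances(42, 7)), 42)
  expect_error(reference_resistances(100, c(1, 0)), "positive")
})

test_that("rescale_preserve_total fixes the parallel total, keeps ratios", {
  r <- c(4, 4)
  expect_equal(rescale_preserve_total(r, 1), c(2, 2))
  r0 <- c(100, 250, 375)
  expect_equal(rescale_preserve_total(r0, 1 / sum(1 / r0)), r0)
  r1 <- rescale_preserve_total(r0, 37)
  expect_equal(r1 / r0, rep(r1[1] / r0[1], 3), tolerance = 1e-14)
  expect_equal(1 / sum(1 / r1), 37, tolerance = 1e-12)
})

test_that("flow_loglik reproduces the Gaussian density", {
  sig <- matrix(c(4, 1, 1, 2), 2)
  tg <- structure(list(mean = c(10, 20), sigma = sig,
                       outlet_ids = 1:2), class = "flow_target_set")
  ident <- function(r) r
  # residual zero: the maximum, -1/2 log((2 pi)^Nc det Sigma)
  lmax <- -0.5 * (2 * log(2 * pi) + log(det(sig)))
  expect_equal(flow_loglik(c(10, 20), tg, ident), lmax, tolerance = 1e-12)

  # univariate: residual k sigma is maximum minus k^2/2
  tg1 <- structure(list(mean = 5, sigma = matrix(9, 1, 1), outlet_ids = 1),
                   class = "flow_target_set")
  l0 <- flow_loglik(5, tg1, ident)
  expect_equal(flow_loglik(5 + 2 * 3, tg1, ident), l0 - 2, tolerance = 1e-12)

  # diagonal Sigma equals the sum of univariate log densities (oracle)
  dsig <- diag(c(4, 9, 16))
  tgd <- structure(list(mean = c(1, 2, 3), sigma = dsig, outlet_ids = 1:3),
                   class = "flow_target_set")
  r <- c(1.7, 0.4, 5.5)
  oracle <- sum(stats::dnorm(r, c(1, 2, 3), c(2, 3, 4), log = TRUE))
  expect_equal(flow_loglik(r, tgd, ident), oracle, tolerance = 1e-12)

  # non-finite model output: -Inf with diagnostic
  bad <- flow_loglik(c(1, 1, 1), tgd, function(r) c(NaN, 1, 1))
  expect_identical(as.numeric(bad), -Inf)
  expect_match(attr(bad, "diagnostic"), "non-finite")
})

test_that("gelman_rubin agrees with an independent textbook implementation", {
  # independent split R-hat written from the standard formula
  split_rhat_oracle <- function(mat) {    # generations x chains
    half <- floor(nrow(mat) / 2)
    seqs <- cbind(mat[1:half, ], mat[(nrow(mat) - half + 1):nrow(mat), ])
    n <- half
    mns <- colMeans(seqs); vrs <- apply(seqs, 2, stats::var)
    W <- mean(vrs); B <- n * stats::var(mns)
    sqrt(((n - 1) / n * W + B / n) / W)
  }
  set.seed(31)
  for (rep in 1:5) {
    arr <- array(rnorm(200 * 4 * 3), c(200, 4, 3))
    got <- gelman_rubin(arr)
    want <- vapply(1:3, function(j) split_rhat_oracle(arr[, , j]), 0)
    expect_equal(got, want, tolerance = 1e-10)
  }

  # identical chains: within-half variation only, R-hat = 1 up to the
  # (n-1)/n finite-sample factor and the between-half term
  one <- matrix(rnorm(100), 100, 1)
  same <- array(c(one, one, one), c(100, 3, 1))
  expect_equal(gelman_rubin(same), 1, tolerance = 0.05)

  # disjoint supports: far above the 1.1 threshold
  bi <- array(c(rnorm(100), rnorm(100) + 50), c(100, 2, 1))
  expect_gt(gelman_rubin(bi), 1.1)

  expect_error(gelman_rubin(array(1, c(100, 1, 2))), "2 chains")
})

test_that("flat likelihood recovers the uniform prior (unconstrained)", {
  prior <- prior_spec(c(100, 200, 50))
  post <- dream_sample(function(r) 0, prior, n_chains = 8,
                       n_generations = 3000, seed = 4,
                       preserve_total = FALSE)
  draws <- posterior_draws(post, thin = 40)   # decorrelate for the KS test
  for (j in 1:3) {
    lo <- 0.5 * prior$r_hat[j]; hi <- 2 * prior$r_hat[j]
    u <- (draws[, j] - lo) / (hi - lo)
    expect_gt(suppressWarnings(stats::ks.test(u, "punif"))$p.value, 0.01)
  }
})

test_that("DREAM matches the conjugate Gaussian posterior (2 outlets)", {
  # identity flow model + Gaussian likelihood + wide prior ~ exact Gaussian
  mu <- c(100, 140); sig <- matrix(c(25, 10, 10, 36), 2)
  tg <- structure(list(mean = mu, sigma = sig, outlet_ids = 1:2),
                  class = "flow_target_set")
  prior <- prior_spec(c(110, 130), lower = 0.25, upper = 4)
  post <- dream_sample(function(r) flow_loglik(r, tg, identity), prior,
                       n_chains = 10, n_generations = 1500, seed = 9,
                       preserve_total = FALSE)
  draws <- posterior_draws(post)
  # MC standard error from independent per-chain means
  chm <- apply(post$chains[(post$burn_gen + 1):post$n_generations, , ],
               c(2, 3), mean)
  se <- apply(chm, 2, stats::sd) / sqrt(post$n_chains)
  expect_true(all(abs(colMeans(draws) - mu) < 3 * se))
  expect_equal(unname(stats::cov(draws)), unname(sig), tolerance = 0.25)
})

test_that("chains are reproducible bit-for-bit and stagnation errors fire", {
  prior <- prior_spec(c(10, 20))
  ll <- function(r) -sum((r - c(12, 18))^2) / 50
  p1 <- dream_sample(ll, prior, n_chains = 6, n_generations = 100, seed = 77)
  p2 <- dream_sample(ll, prior, n_chains = 6, n_generations = 100, seed = 77)
  expect_identical(p1$chains, p2$chains)
  expect_warning(dream_sample(ll, prior, n_chains = 3, n_generations = 20,
                              seed = 1), "mixing")
  # impossible likelihood: every proposal rejected -> stagnation diagnostic
  expect_error(
    dream_sample(function(r) -Inf, prior, n_chains = 6,
                 n_generations = 600, seed = 2, stagnation_window = 200),
    "stagnation")
})

test_that("small recovery problem: posterior concentrates near the truth", {
  prob <- small_recovery()
  ll <- function(r) flow_loglik(r, prob$targets, prob$model)
  post <- dream_sample(ll, prob$prior, n_chains = 12, n_generations = 1000,
                       seed = 21)
  draws <- posterior_draws(post, thin = 5)

  # every retained sample satisfies the total-resistance constraint
  tot <- apply(draws, 1, function(r) 1 / sum(1 / r))
  expect_lt(max(abs(tot - prob$prior$total_resistance)) /
              prob$prior$total_resistance, 1e-10)

  # componentwise recovery of the generating resistances within 5%
  expect_lt(max(abs(colMeans(draws) - prob$r_star) / prob$r_star), 0.05)

  # posterior predictive flows match the targets within 1 predictive sd
  pp <- posterior_predictive_flows(post, prob$model, thin = 20)
  expect_true(all(abs(pp$mean - prob$targets$mean) <= pmax(pp$sd, 1e-9)))

  # unimodal marginals (kernel-density mode count)
  n_modes <- function(x) {
    d <- stats::density(x, adjust = 1.5)
    sum(diff(sign(diff(d$y))) == -2)
  }
  expect_true(all(apply(draws, 2, n_modes) == 1))

  # predictive covariance reproduces the sign of the dominant target
  # covariances
  SC <- prob$targets$sigma; diag(SC) <- 0
  top <- which(abs(SC) == max(abs(SC)), arr.ind = TRUE)[1, ]
  expect_equal(sign(pp$covariance[top[1], top[2]]),
               sign(SC[top[1], top[2]]))
})

test_that("cardiac tuner improves the match to its targets", {
  net <- build_network(small_tree())
  fit <- tune_cardiac_function(net, targets = list(sbp = 125, dbp = 78),
                               params = c("lv_emax", "systemic_resistance"),
                               n_cycles = 2, steps_per_cycle = 150,
                               maxit = 10)
  expect_true(is.finite(fit$value))
  expect_true(all(c("sbp", "dbp", "stroke_volume", "ef") %in%
                    names(fit$metrics)))
  expect_s3_class(fit$net, "circuit_network")
})
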