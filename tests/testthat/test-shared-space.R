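# Autoencoders, 1D flows, shared-space resampling.

make_ident_mlp <- function(scale = 1) {
  # single linear layer computing scale * x (for hand-built maps)
  net <- coroUQ:::mlp_init(c(1, 1))
  net$W[[1]][1, 1] <- scale; net$b[[1]] <- 0
  net
}

test_that("flow transform: normality, median, round trip, monotonicity", {
  set.seed(2)
  z <- rgamma(400, shape = 2)          # skewed latent distribution
  fl <- fit_flow(z)
  g <- flow_forward(fl, z)
  expect_gt(suppressWarnings(stats::ks.test(g, "pnorm"))$p.value, 0.01)
  expect_lt(abs(flow_forward(fl, stats::median(z))), 0.05)
  # round trip on the training range
  zi <- seq(stats::quantile(z, 0.01), stats::quantile(z, 0.99),
            length.out = 200)
  expect_equal(flow_inverse(fl, flow_forward(fl, zi)), zi, tolerance = 1e-6)
  # strict monotonicity
  expect_true(all(diff(flow_forward(fl, sort(z))) >= 0))
  expect_error(fit_flow(rep(3, 100)), "degenerate")
  expect_error(fit_flow(rnorm(5)), "20")
})

test_that("stage-1 gradients match finite differences", {
  set.seed(7)
  n <- 12; d <- 3
  X <- matrix(rnorm(n * d), n, d); y <- matrix(rnorm(n), ncol = 1)
  enc <- coroUQ:::mlp_init(c(d, 4, 1))
  dec <- coroUQ:::mlp_init(c(1, 4, d))
  head <- coroUQ:::mlp_init(c(1, 4, 1))
  ps <- coroUQ:::stage1_pass(enc, dec, head, X, y)
  num_grad <- function(net, which_l, i, j, setter) {
    h <- 1e-6
    net1 <- net; net1$W[[which_l]][i, j] <- net1$W[[which_l]][i, j] + h
    nets <- setter(net1)
    l1 <- coroUQ:::stage1_pass(nets$enc, nets$dec, nets$head, X, y,
                               backward = FALSE)$loss
    net2 <- net; net2$W[[which_l]][i, j] <- net2$W[[which_l]][i, j] - h
    nets <- setter(net2)
    l2 <- coroUQ:::stage1_pass(nets$enc, nets$dec, nets$head, X, y,
                               backward = FALSE)$loss
    (l1 - l2) / (2 * h)
  }
  for (probe in list(
    list(part = "enc", l = 1, i = 2, j = 3),
    list(part = "enc", l = 2, i = 1, j = 4),
    list(part = "dec", l = 2, i = 3, j = 2),
    list(part = "head", l = 1, i = 4, j = 1))) {
    net <- switch(probe$part, enc = enc, dec = dec, head = head)
    setter <- switch(probe$part,
      enc = function(n2) list(enc = n2, dec = dec, head = head),
      dec = function(n2) list(enc = enc, dec = n2, head = head),
      head = function(n2) list(enc = enc, dec = dec, head = n2))
    want <- num_grad(net, probe$l, probe$i, probe$j, setter)
    got <- switch(probe$part, enc = ps$genc, dec = ps$gdec,
                  head = ps$ghead)$dW[[probe$l]][probe$i, probe$j]
    expect_equal(got, want, tolerance = 1e-5)
  }
})

test_that("stage-1 learns single-coordinate and rotated 1D active subspaces", {
  cfg <- ae_config(epochs = 1500, stage2_epochs = 0, patience = 1e9)
  set.seed(11)
  n <- 400; d <- 5
  X <- matrix(rnorm(n * d), n, d)
  Xt <- matrix(rnorm(1000 * d), 1000, d)

  # QoI depends on a single input coordinate, others are noise
  f1 <- function(M) M[, 2] + 0.3 * M[, 2]^3
  m1 <- train_stage1(X, f1(X), cfg, seed = 3)
  r2 <- function(m, f) {
    pred <- ae_predict(m, Xt); 1 - mean((f(Xt) - pred)^2) / var(f(Xt))
  }
  expect_gt(r2(m1, f1), 0.95)

  # rotated linear active subspace
  w <- rep(1, d) / sqrt(d)
  f2 <- function(M) drop(M %*% w) + 0.3 * drop(M %*% w)^3
  m2 <- train_stage1(X, f2(X), cfg, seed = 4)
  expect_gt(r2(m2, f2), 0.95)

  # reconstruction idempotence: ||DE(x) - DEDE(x)|| below 10% of scale
  Xs <- coroUQ:::std_apply(Xt, m2$x_center, m2$x_scale)
  e <- coroUQ:::mlp_forward(m2$enc, Xs)$out
  xr <- coroUQ:::mlp_forward(m2$dec, e)$out
  er <- coroUQ:::mlp_forward(m2$enc, xr)$out
  xrr <- coroUQ:::mlp_forward(m2$dec, er)$out
  expect_lt(sqrt(mean((xr - xrr)^2)), 0.1)
})

test_that("degenerate identity chain reproduces the LF model exactly", {
  # hand-built map: 1D input, identity encoders/decoders, flows fitted on
  # the same samples -> the composed chain is the identity on the support
  set.seed(9)
  z <- rnorm(200)
  fl <- fit_flow(z)
  mk_model <- function() {
    structure(list(enc = make_ident_mlp(), dec = make_ident_mlp(),
                   head = make_ident_mlp(),
                   x_center = 0, x_scale = 1, y_center = 0, y_scale = 1,
                   d = 1, config = ae_config()), class = "ae_model")
  }
  lf_fun <- function(M) 2 * drop(as.matrix(M)) + 1
  map <- structure(list(hf = mk_model(), lf = mk_model(),
                        flow_hf = fl, flow_lf = fl, flip = FALSE,
                        lf_fun = lf_fun), class = "shared_space_map")
  xin <- matrix(sort(z)[10:190], ncol = 1)   # interior of the support
  got <- resample_lf(map, xin)
  expect_equal(as.numeric(got), lf_fun(xin), tolerance = 1e-9)
  expect_equal(length(got), nrow(xin))
  # deterministic for a fixed map
  expect_equal(as.numeric(resample_lf(map, xin)), as.numeric(got))
})

test_that("stage-2 raises the correlation on a weakly correlated pair", {
  cfg <- ae_config(epochs = 700, stage2_epochs = 400, patience = 15)
  pair <- fixture_pair(0.1)
  map <- train_shared_space(pair, n_pilot = 150, n_lf = 300, config = cfg,
                            seed = 5)
  expect_gt(abs(map$rho_ae), abs(map$rho))
  expect_gt(map$rho_ae, 0)          # canonical orientation
  expect_lt(abs(map$rho), 0.4)

  # lf == hf with identical AEs: resampled correlation ~ 1
  pair_same <- pair; pair_same$lf_fun <- pair$hf_fun
  map_s <- train_shared_space(pair_same, n_pilot = 150, n_lf = 0,
                              config = cfg, seed = 6)
  expect_gt(map_s$rho, 0.999)
  # smoke-scale training budget; the full-scale bound lives in
  # test-acceptance.R
  expect_gt(map_s$rho_ae, 0.9)

  # mfmc_ae_estimate: alpha = 0 reduces to MC on the HF values
  X2 <- with_seed(31, pair$sample_inputs(80))
  hf2 <- pair$hf_fun(X2)
  extra <- with_seed(32, pair$sample_inputs(200))
  e0 <- mfmc_ae_estimate(map, X2, hf2, extra, alpha = 0)
  expect_equal(e0$mean, mean(hf2))
  e1 <- mfmc_ae_estimate(map, X2, hf2, extra)
  expect_equal(e1$estimator, "MFMC-AE")
  expect_lt(e1$variance, mc_estimate(hf2)$variance)
})

test_that("latent dimension above one is rejected", {
  expect_error(ae_config(latent_dim = 2), "not supported")
})

test_that("convergence study is reproducible and spans pilot sizes", {
  cfg <- ae_config(epochs = 120, stage2_epochs = 80, patience = 5)
  pair <- fixture_pair(0.6)
  cs1 <- convergence_study(pair, pilot_sizes = c(25, 60), n_trials = 2,
                           seed = 17, config = cfg)
  cs2 <- convergence_study(pair, pilot_sizes = c(25, 60), n_trials = 2,
                           seed = 17, config = cfg)
  expect_identical(cs1$trials, cs2$trials)
  expect_equal(nrow(cs1$trials), 4)
  expect_true(all(is.finite(cs1$trials$rho_ae)))
  expect_equal(cs1$summary$pilot_size, c(25, 60))
})
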