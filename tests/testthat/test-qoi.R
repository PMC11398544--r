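# Wall-shear metrics, FFR, input sampling, high-fidelity surrogate.

test_that("tawss: constants, |sin| closed form, homogeneity, refinement", {
  t1 <- seq(0, 1, length.out = 1001)
  expect_equal(tawss(rep(10, 1001), t1), 10, tolerance = 1e-12)
  expect_equal(tawss(sin(2 * pi * t1), t1), 2 / pi, tolerance = 1e-5)
  tau <- 3 + sin(2 * pi * t1)
  expect_equal(tawss(-2.5 * tau, t1), 2.5 * tawss(tau, t1), tolerance = 1e-12)
  # quadrature refinement invariance on a smooth waveform
  t2 <- seq(0, 1, length.out = 4001)
  expect_equal(tawss(3 + sin(2 * pi * t2), t2), tawss(tau, t1),
               tolerance = 1e-6)
})

test_that("osi attains its bounds and the hand-integrated case", {
  t1 <- seq(0, 1, length.out = 1001)
  expect_equal(osi(rep(4, 1001), t1), 0)
  expect_equal(osi(sin(2 * pi * t1), t1), 0.5, tolerance = 1e-9)
  # +1 on [0, 0.75T], -1 after: OSI = (1 - 0.5)/2 = 0.25
  tau <- ifelse(t1 <= 0.75, 1, -1)
  expect_equal(osi(tau, t1), 0.25, tolerance = 1e-2)
  expect_warning(z <- osi(rep(0, 1001), t1), "zero")
  expect_equal(z, 0)
  # vector-valued waveform: rotating shear of constant magnitude
  tau2 <- cbind(cos(2 * pi * t1), sin(2 * pi * t1))
  expect_equal(osi(tau2, t1), 0.5, tolerance = 1e-4)
})

test_that("osi stays within [0, 0.5] for random admissible waveforms", {
  set.seed(5)
  t1 <- seq(0, 1, length.out = 257)
  for (k in 1:50) {
    tau <- rnorm(1) + 3 * sin(2 * pi * sample(1:4, 1) * t1 + runif(1)) +
      rnorm(257, sd = 0.5)
    v <- osi(tau, t1)
    expect_gte(v, 0); expect_lte(v, 0.5)
  }
})

test_that("ffr definition and 0D extraction behave", {
  expect_equal(ffr(80, 100), 0.8)
  t1 <- seq(0, 0.8, length.out = 401)
  pa <- 100 + 20 * sin(2 * pi * t1 / 0.8)
  expect_equal(ffr(pa, pa, t1), 1.0)
  expect_error(ffr(1, -1), "aortic")

  # single stenosed branch: FFR from the steady network, monotone in S
  tr <- data.frame(branch_id = 1, parent_id = 0, length_cm = 2,
                   diameter_cm = 0.3, stenosis_severity = 0.5,
                   outlet_flag = 1, perfuses_LV_flag = 1,
                   outlet_x = 0, outlet_y = 0, outlet_z = 1)
  net <- build_network(tr)
  f1 <- qoi_from_0d(steady_flow_split(net), "ffr:1")
  tr$stenosis_severity <- 0.7
  f2 <- qoi_from_0d(steady_flow_split(build_network(tr)), "ffr:1")
  expect_true(f2 < f1, TRUE)
  expect_true(f1 > 0 && f1 <= 1)

  # no stenosis and negligible branch resistance: FFR ~ 1
  tr$stenosis_severity <- 0; tr$length_cm <- 0.05; tr$diameter_cm <- 0.5
  f3 <- qoi_from_0d(steady_flow_split(build_network(tr)), "ffr:1")
  expect_gt(f3, 0.999)
})

test_that("qoi_from_0d dispatches mean flow, shear metrics, custom", {
  net <- small_net()
  st <- steady_flow_split(net)
  oid <- as.character(lv_outlet_ids(net)[1])
  expect_equal(qoi_from_0d(st, paste0("mean_flow:", oid)),
               unname(st$segment_flows[oid]))
  res <- suppressWarnings(simulate_zerod(net, n_cycles = 2,
                                         steps_per_cycle = 200))
  expect_equal(qoi_from_0d(res, paste0("mean_flow:", oid)),
               mean(res$flows[, oid]))
  v_osi <- qoi_from_0d(res, paste0("osi:", oid))
  expect_gte(v_osi, 0); expect_lte(v_osi, 0.5)
  expect_gt(qoi_from_0d(res, paste0("tawss:", oid)), 0)
  expect_error(qoi_from_0d(st, "banana:1"), "unknown QoI")
  expect_equal(qoi_from_0d(st, function(r) 42), 42)
})

test_that("sample_inputs respects the s support and reproducibility", {
  draws <- matrix(rexp(50 * 3) + 1, 50, 3)
  th1 <- sample_inputs(draws, 2000, seed = 6)
  th2 <- sample_inputs(draws, 2000, seed = 6)
  expect_identical(unclass(th1), unclass(th2))
  s <- th1[, "s"]
  expect_true(all(s >= 0.7 & s <= 1.25))
  # mean of U(0.7, 1.25) = 0.975
  expect_lt(abs(mean(s) - 0.975), 3 * stats::sd(s) / sqrt(2000))
})

test_that("hf surrogate: degenerate pair, distortion, table lookup", {
  net <- small_net()
  oid <- as.character(lv_outlet_ids(net)[1])
  spec <- paste0("mean_flow:", oid)
  draws <- matrix(rep(outlet_resistances(net)[as.character(lv_outlet_ids(net))],
                      each = 30) * exp(matrix(rnorm(30 * 6, 0, 0.2), 30)),
                  nrow = 30)
  th <- sample_inputs(draws, 60, seed = 3)

  lf <- vapply(seq_len(nrow(th)), function(i) {
    neti <- coroUQ:::apply_inputs_to_network(net, th[i, 1:6], th[i, 7])
    qoi_from_0d(steady_flow_split(neti), spec)
  }, 0)

  # distortion off, same inner model: HF == LF exactly
  cfg0 <- hf_surrogate_config(net, spec, inner = "steady",
                              distortion = "none")
  expect_equal(hf_surrogate(th, cfg0), lf, tolerance = 1e-12)

  # OSI-proxy distortion: non-monotone in the mean flow -> weak correlation
  cfg1 <- hf_surrogate_config(net, spec, inner = "steady",
                              distortion = "osi_proxy",
                              calibrate_inputs = th)
  hf <- hf_surrogate(th, cfg1)
  expect_true(all(hf >= 0 & hf <= 0.5))
  expect_lt(abs(stats::cor(hf, lf)), 0.7)

  # table-backed mode reproduces supplied values exactly and errors on miss
  tb <- data.frame(matrix(th, nrow = nrow(th)))
  names(tb) <- paste0("theta_", seq_len(ncol(th)))
  tb$qoi <- seq_len(nrow(th)) * 1.5
  p <- tempfile(fileext = ".csv"); write.csv(tb, p, row.names = FALSE)
  cfg2 <- hf_surrogate_config(net, spec, table = read_hf_table(p))
  expect_equal(hf_surrogate(th, cfg2), tb$qoi)
  miss <- th; miss[1, 1] <- miss[1, 1] * 3
  expect_error(hf_surrogate(miss, cfg2), "miss")
})
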