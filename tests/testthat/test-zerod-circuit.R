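# 0D circuit construction, element laws, and both solvers.

test_that("build_network maps branches to segments with geometric scaling", {
  net <- build_network(symmetric_tree())
  seg <- net$segments
  expect_equal(seg$R[2], seg$R[3])
  expect_equal(seg$C[2], seg$C[3])
  expect_equal(seg$L[2], seg$L[3])
  expect_true(all(seg$S == 0))

  # halving diameter at fixed length: R increases 2^4 = 16x (Poiseuille)
  net2 <- build_network(symmetric_tree(d_child = 0.125))
  expect_equal(net2$segments$R[2] / seg$R[2], 16, tolerance = 1e-12)

  # stenosed branches receive S > 0
  net3 <- build_network(symmetric_tree(sev = 0.5))
  expect_true(all(net3$segments$S[2:3] > 0))
})

test_that("tree validation rejects broken anatomies", {
  tr <- symmetric_tree()
  tr$parent_id[2] <- 99
  expect_error(build_network(tr), "unknown parent")
  tr <- symmetric_tree(); tr$length_cm[1] <- -1
  expect_error(build_network(tr), "nonpositive")
  tr <- symmetric_tree(); tr$outlet_flag[2] <- 0
  expect_error(build_network(tr), "terminal")
})

test_that("stenosis pressure loss is quadratic and odd", {
  expect_equal(stenosis_pressure_loss(100, 2), 400)
  expect_equal(stenosis_pressure_loss(100, -2), -400)
  expect_equal(stenosis_pressure_loss(0, 17.3), 0)
  expect_error(stenosis_pressure_loss(-1, 1))
})

test_that("chamber elastance pressure model behaves at its edges", {
  ch <- heart_chamber(2000, 100, activation_onset = 0.1,
                      activation_duration = 0.3, unstressed_volume = 10)
  # outside the activation window: P = E_min (V - V0)
  expect_equal(chamber_pressure(ch, 60, t = 0.9 * 0.8, period = 0.8),
               100 * 50)
  # E_max = E_min: constant in t
  ch2 <- heart_chamber(100, 100)
  ts <- seq(0, 0.79, length.out = 23)
  expect_equal(chamber_pressure(ch2, 60, ts, 0.8), rep(100 * 55, 23))
  # V = V0: zero pressure at all t
  expect_equal(chamber_pressure(ch, 10, ts, 0.8), rep(0, 23))
  # time reduced modulo the period
  expect_equal(elastance_at(ch, 0.25, 0.8), elastance_at(ch, 0.25 + 3 * 0.8, 0.8))
})

test_that("murray_resistance_split preserves the parallel total", {
  expect_equal(murray_resistance_split(1000, c(0.3, 0.3)), c(2000, 2000))
  r <- murray_resistance_split(500, c(0.4, 0.2))
  expect_equal(r[2] / r[1], 2^2.6, tolerance = 1e-12)
  expect_equal(1 / sum(1 / r), 500, tolerance = 1e-12)
  expect_equal(murray_resistance_split(777, 0.35), 777)
  expect_error(murray_resistance_split(100, numeric(0)), "empty")
})

test_that("apply_hyperemia scales Ra, Ramicro and Rv only", {
  base <- build_network(small_tree())
  same <- apply_hyperemia(base, 1)
  expect_identical(same$coronary_bc, base$coronary_bc)
  hyp <- apply_hyperemia(base, 0.24)
  expect_equal(hyp$coronary_bc$Ra, 0.24 * base$coronary_bc$Ra)
  expect_equal(hyp$coronary_bc$Ramicro, 0.24 * base$coronary_bc$Ramicro)
  expect_equal(hyp$coronary_bc$Rv, 0.24 * base$coronary_bc$Rv)
  expect_identical(hyp$segments, base$segments)
  # halving resistance increases total coronary flow (monotonicity)
  q1 <- sum(steady_flow_split(apply_hyperemia(base, 0.5))$outlet_flows)
  q2 <- sum(steady_flow_split(apply_hyperemia(base, 0.24))$outlet_flows)
  q0 <- sum(steady_flow_split(base)$outlet_flows)
  expect_true(q0 < q1 && q1 < q2)
})

test_that("steady solver matches the dense nodal oracle (linear limit)", {
  net <- small_net()
  # remove stenoses for the linear case
  net$segments$S[] <- 0
  p_in <- mmHg_to_dyncm2(90); p_v <- mmHg_to_dyncm2(5)
  sol <- steady_flow_split(net, p_inlet = p_in, p_venous = p_v)
  ora <- steady_oracle(net, p_in, p_v)
  expect_equal(unname(sol$segment_flows), ora$flows, tolerance = 1e-9)
  expect_equal(unname(sol$node_pressures), ora$pressures, tolerance = 1e-9)
})

test_that("steady solver: single resistor obeys Ohm's law; stenosis adds S|Q|Q", {
  tr <- data.frame(branch_id = 1, parent_id = 0, length_cm = 2,
                   diameter_cm = 0.3, stenosis_severity = 0, outlet_flag = 1,
                   perfuses_LV_flag = 1, outlet_x = 0, outlet_y = 0,
                   outlet_z = 1)
  net <- build_network(tr)
  sol <- steady_flow_split(net, p_inlet = 1e5, p_venous = 0)
  Rtot <- net$segments$R[1] + sum(unlist(
    net$coronary_bc[1, c("Ra", "Ramicro", "Rv")]))
  expect_equal(unname(sol$outlet_flows), 1e5 / Rtot, tolerance = 1e-10)

  tr$stenosis_severity <- 0.6
  nets <- build_network(tr)
  sols <- steady_flow_split(nets, p_inlet = 1e5, p_venous = 0)
  Q <- unname(sols$outlet_flows)
  S <- nets$segments$S[1]
  # pressure balance including the quadratic loss closes exactly
  expect_equal(1e5, Q * Rtot + S * Q^2, tolerance = 1e-8)
  expect_true(Q < unname(sol$outlet_flows))
})

test_that("outlet resistance monotonicity: raising one outlet's resistance", {
  net <- small_net()
  ids <- lv_outlet_ids(net)
  r0 <- outlet_resistances(net)[as.character(ids)]
  f0 <- steady_flow_split(net)$outlet_flows
  r1 <- r0; r1[3] <- r1[3] * 2
  f1 <- steady_flow_split(net, r_outlets = stats::setNames(r1, ids))$outlet_flows
  expect_lt(f1[[as.character(ids[3])]], f0[[as.character(ids[3])]])
  others <- setdiff(names(f0), as.character(ids[3]))
  expect_true(all(f1[others] >= f0[others]))
})

test_that("transient solver conserves mass and reaches a periodic state", {
  net <- small_net()
  res <- suppressWarnings(simulate_zerod(net, n_cycles = 6,
                                         steps_per_cycle = 500))
  roots <- which(net$parent == 0)
  qin <- sum(colMeans(res$flows[, roots, drop = FALSE]))
  qout <- sum(res$mean_outlet_flows)
  expect_lt(abs(qin - qout) / qin, 0.005)
  expect_lt(res$convergence, 0.02)
  expect_true(all(is.finite(res$pressures)))
  expect_equal(nrow(res$pressures), 500)
  # coronary flow is diastolic-dominant: systolic intramyocardial pressure
  # impedes inflow, so mean LV-outlet inflow in systole < in diastole
  lv_cols <- as.character(lv_outlet_ids(net))
  syst <- res$time - min(res$time) < 0.38 * res$period
  q_lv <- rowSums(res$outlet_flows[, lv_cols, drop = FALSE])
  expect_lt(mean(q_lv[syst]), mean(q_lv[!syst]))
})

test_that("transient grid convergence: halving the step changes means < 1%", {
  net <- small_net()
  r1 <- suppressWarnings(simulate_zerod(net, n_cycles = 4,
                                        steps_per_cycle = 400))
  r2 <- suppressWarnings(simulate_zerod(net, n_cycles = 4,
                                        steps_per_cycle = 800))
  rel <- abs(r1$mean_outlet_flows - r2$mean_outlet_flows) /
    abs(r2$mean_outlet_flows)
  expect_lt(max(rel), 0.01)
})

test_that("windkessel discharge matches the closed-form decay constant", {
  C <- 1.2e-3; Rd <- 1400; P0 <- mmHg_to_dyncm2(95)
  tau <- Rd * C
  times <- seq(0, 3 * tau, length.out = 600)
  p <- windkessel_discharge(C, Rd, P0, times)
  expect_equal(p, P0 * exp(-times / tau), tolerance = 1e-4)
  # fitted decay constant within 1%
  fit <- -1 / stats::coef(stats::lm(log(p) ~ times))[["times"]]
  expect_lt(abs(fit - tau) / tau, 0.01)
})

test_that("result export writes the documented CSV schema", {
  net <- small_net()
  res <- suppressWarnings(simulate_zerod(net, n_cycles = 2,
                                         steps_per_cycle = 120))
  path <- tempfile(fileext = ".csv")
  result_to_csv(res, path)
  df <- read.csv(path)
  expect_named(df, c("time", "node", "pressure_mmHg", "flow_mL_per_s"))
  expect_true(all(is.na(df$flow_mL_per_s[df$node == "aorta"])))
  expect_equal(nrow(df), 120 * (nrow(net$segments) + 1))
})
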