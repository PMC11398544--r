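# Territory assignment, MBF integration, and target uncertainty statistics.

# toy LV cloud with hand-chosen points and two outlets on the x axis
toy_lv <- function(pts, vv = 1, mbf = 1) {
  structure(list(points = pts, voxel_volume = vv,
                 mbf = rep(mbf, length.out = nrow(pts))), class = "lv_cloud")
}
toy_outlets <- function(coords, lv = TRUE) {
  o <- data.frame(outlet_id = seq_len(nrow(coords)), x = coords[, 1],
                  y = coords[, 2], z = coords[, 3],
                  perfuses_LV = rep(lv, length.out = nrow(coords)))
  structure(o, Nc = sum(o$perfuses_LV), class = c("outlet_set", "data.frame"))
}

test_that("single outlet captures all points at any noise level", {
  lv <- toy_lv(matrix(rnorm(60), 20, 3))
  out <- toy_outlets(matrix(c(5, 0, 0), 1, 3))
  for (frac in c(0, 0.5)) {
    a <- assign_territories(lv, out, distance_noise = frac, seed = 1)
    expect_true(all(a$index == 1))
  }
})

test_that("deterministic assignment is exact nearest-neighbour with tie rule", {
  # brute-force all-pairs oracle
  set.seed(42)
  pts <- matrix(runif(300, -2, 2), 100, 3)
  oc <- matrix(runif(15, -2, 2), 5, 3)
  lv <- toy_lv(pts); out <- toy_outlets(oc)
  a <- assign_territories(lv, out, distance_noise = 0)
  brute <- apply(pts, 1, function(p)
    which.min(apply(oc, 1, function(o) sqrt(sum((p - o)^2)))))
  expect_equal(a$index, unname(brute))

  # exact tie between outlets 2 and 5 -> lower index wins
  oc2 <- rbind(c(9, 9, 9), c(1, 0, 0), c(9, -9, 9), c(-9, 0, 9), c(-1, 0, 0))
  lv2 <- toy_lv(matrix(0, 1, 3))   # equidistant to outlets 2 and 5
  a2 <- assign_territories(lv2, toy_outlets(oc2), distance_noise = 0)
  expect_equal(a2$index, 2L)
})

test_that("territory volumes partition the LV exactly", {
  lv <- generate_lv(400, seed = 3)
  out <- outlet_set(generate_tree(10, seed = 3))
  a <- assign_territories(lv, out, distance_noise = 0.1, seed = 5)
  expect_equal(sum(a$volumes), a$total_volume, tolerance = 1e-12)
  expect_equal(length(a$index), 400)
})

test_that("branch flows integrate MBF over territories", {
  # territories with 2, 3, 5 points, unit mbf and voxel volume
  pts <- rbind(matrix(c(-5, 0, 0), 2, 3, byrow = TRUE),
               matrix(c(0, 5, 0), 3, 3, byrow = TRUE),
               matrix(c(5, 0, 0), 5, 3, byrow = TRUE))
  pts <- pts + matrix(runif(30, -0.1, 0.1), 10, 3)
  lv <- toy_lv(pts)
  out <- toy_outlets(rbind(c(-5, 0, 0), c(0, 5, 0), c(5, 0, 0)))
  a <- assign_territories(lv, out, distance_noise = 0)
  f <- branch_flows(lv, a, mbf_noise = 0)
  expect_equal(unname(f), c(2, 3, 5))
  # conservation: flows sum exactly to total LV flow
  expect_equal(sum(f), total_lv_flow(lv), tolerance = 1e-12)
})

test_that("MBF-noise flow sd follows the closed form 0.2 q sqrt(m)", {
  m <- 400
  lv <- toy_lv(matrix(rnorm(3 * m, sd = 0.2), m, 3), vv = 0.5, mbf = 2)
  out <- toy_outlets(matrix(c(0, 0, 0), 1, 3))
  a <- assign_territories(lv, out, distance_noise = 0)
  set.seed(10)
  fs <- vapply(1:2000, function(k) branch_flows(lv, a, mbf_noise = 0.2,
                                                seed = k), 0)
  q <- 2 * 0.5                       # per-point flow
  expect_equal(stats::sd(fs), 0.2 * q * sqrt(m), tolerance = 0.05)
})

test_that("build_flow_targets: zero noise collapses to the deterministic flows", {
  lv <- generate_lv(300, seed = 8)
  out <- outlet_set(generate_tree(8, seed = 8))
  tg <- build_flow_targets(lv, out, n_realizations = 5, distance_noise = 0,
                           mbf_noise = 0, seed = 1)
  a <- assign_territories(lv, out, distance_noise = 0)
  f <- branch_flows(lv, a, mbf_noise = 0)
  expect_equal(unname(tg$mean), unname(f), tolerance = 1e-12)
  expect_true(all(tg$sigma == 0))
})

test_that("covariance structure reflects the noise sources", {
  lv <- generate_lv(800, seed = 12)
  out <- outlet_set(generate_tree(8, seed = 12))

  # MBF noise only: independent per-territory sums -> near-diagonal Sigma
  tg_m <- build_flow_targets(lv, out, n_realizations = 400,
                             distance_noise = 0, mbf_noise = 0.2, seed = 2)
  off <- tg_m$sigma; diag(off) <- 0
  expect_lt(max(abs(off)) / max(diag(tg_m$sigma)), 0.15)

  # distance noise couples adjacent territories -> clearly non-diagonal
  tg_d <- build_flow_targets(lv, out, n_realizations = 400,
                             distance_noise = 0.1, mbf_noise = 0.2, seed = 2)
  offd <- tg_d$sigma; diag(offd) <- 0
  expect_gt(max(abs(offd)) / max(diag(tg_d$sigma)), 0.15)

  # symmetry + PSD; realization diagonal consistent with Sigma
  expect_equal(tg_d$sigma, t(tg_d$sigma))
  expect_gte(min(eigen(tg_d$sigma, symmetric = TRUE)$values),
             -1e-10 * sum(diag(tg_d$sigma)))
  expect_equal(unname(diag(stats::cov(tg_d$realizations))),
               unname(diag(tg_d$sigma)), tolerance = 1e-6)
})

test_that("psd_repair clips negative eigenvalues and keeps PSD intact", {
  S <- matrix(c(1, 0.9, 0.9, 1), 2)
  expect_equal(psd_repair(S), S)
  Sneg <- matrix(c(1, 1.1, 1.1, 1), 2)   # indefinite
  Sr <- psd_repair(Sneg)
  expect_gte(min(eigen(Sr, symmetric = TRUE)$values), 0)
})

test_that("flow targets survive a JSON round trip", {
  lv <- generate_lv(200, seed = 5)
  out <- outlet_set(generate_tree(8, seed = 5))
  tg <- build_flow_targets(lv, out, n_realizations = 50, seed = 3)
  p <- tempfile(fileext = ".json")
  write_flow_targets(tg, p)
  tg2 <- read_flow_targets(p)
  expect_equal(unname(tg2$mean), unname(tg$mean), tolerance = 1e-12)
  expect_equal(unname(tg2$sigma), unname(tg$sigma), tolerance = 1e-12)
  expect_equal(dim(tg2$realizations), dim(tg$realizations))
})
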