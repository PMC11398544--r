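# Shared test fixtures, built in code (no stored data files).

# hand-written symmetric two-branch tree: one root splitting into two
# identical outlet branches
symmetric_tree <- function(d_child = 0.25, sev = 0) {
  data.frame(
    branch_id = 1:3,
    parent_id = c(0, 1, 1),
    length_cm = c(2, 3, 3),
    diameter_cm = c(0.35, d_child, d_child),
    stenosis_severity = c(0, sev, sev),
    outlet_flag = c(0, 1, 1),
    perfuses_LV_flag = c(0, 1, 1),
    outlet_x = c(0, 1, -1), outlet_y = c(0, 0, 0), outlet_z = c(0, 1, 1))
}

small_tree <- function(seed = 1) generate_tree(n_outlets = 8, seed = seed,
                                               n_lv = 6)

small_net <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- apply_hyperemia(build_network(small_tree()))
    cache
  }
})

# independent dense nodal-analysis oracle for the steady resistor network
# (linear case S = 0): solves G p = b for the distal-node pressures with
# per-segment series resistance R and per-outlet distal resistance to the
# venous pressure.
steady_oracle <- function(net, p_in, p_v) {
  seg <- net$segments
  n <- nrow(seg)
  r_bc <- rep(NA_real_, n)
  r_bc[net$coronary_bc$seg] <- net$coronary_bc$Ra + net$coronary_bc$Ramicro +
    net$coronary_bc$Rv
  G <- matrix(0, n, n); b <- numeric(n)
  for (s in seq_len(n)) {
    gs <- 1 / seg$R[s]
    G[s, s] <- G[s, s] + gs
    if (net$parent[s] == 0) b[s] <- b[s] + gs * p_in
    else { G[s, net$parent[s]] <- G[s, net$parent[s]] - gs }
    if (seg$outlet[s]) {
      gb <- 1 / r_bc[s]
      G[s, s] <- G[s, s] + gb
      b[s] <- b[s] + gb * p_v
    } else {
      for (k in which(net$parent == s)) {
        gk <- 1 / seg$R[k]
        G[s, s] <- G[s, s] + gk
        G[s, k] <- G[s, k] - gk
      }
    }
  }
  p <- solve(G, b)
  pprox <- ifelse(net$parent == 0, p_in, p[pmax(net$parent, 1)])
  list(pressures = p, flows = (pprox - p) / seg$R)
}

# cached recovery problem at unit-test scale (smaller than the acceptance
# fixture so the whole suite stays fast)
small_recovery <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_recovery_problem(seed = 7, n_outlets = 8, n_lv = 6,
                                      n_points = 1200, n_realizations = 300)
    cache
  }
})

# correlated bivariate-normal model pair with every quantity known in
# closed form; used for estimator sanity checks
gaussian_pair_draw <- function(n3d, n0d, rho, mu_hf = 2, sd_hf = 1.5) {
  z <- rnorm(n0d)
  w <- rnorm(n0d)
  lf <- z
  hf <- mu_hf + sd_hf * (rho * z + sqrt(1 - rho^2) * w)
  sample_pair_set(hf[seq_len(n3d)], lf[seq_len(n3d)], lf[-seq_len(n3d)])
}
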