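# Transient closed-loop 0D solver.
#
# State vector layout (n = #segments, m = #coronary outlets):
#   [1..n]        segment flows Q (inductor states)
#   [n+1..2n]     segment distal-node pressures P (junction capacitances)
#   [2n+1..2n+4]  chamber volumes V: LA, LV, RA, RV
#   [.. +4]       global pressures: P_ao, Pc_sys, P_ven, Pc_pul
#   [.. +m]       coronary BC proximal capacitor pressures P_a
#   [.. +m]       coronary BC intramyocardial capacitor charge pressures
#                 u = P_node - P_im(t)  (so dP_im/dt never enters the RHS)
#
# The heart is four time-varying elastance chambers with smoothed-diode
# valves (mitral, aortic, tricuspid, pulmonary); systemic and pulmonary beds
# are RCR Windkessels; venous return collects the systemic bed and the
# coronary Rv outflows. The scheme is the generalized trapezoidal rule with
# chord Newton (finite-difference Jacobian, reused across steps).

#' Simulate the closed-loop 0D circulation
#'
#' Integrates the circuit for `n_cycles` cardiac cycles and returns the final
#' cycle's waveforms together with a cycle-to-cycle convergence metric (the
#' maximum relative change of mean aortic pressure and mean outlet flows
#' between the last two cycles; a warning is issued above 1%).
#'
#' @param net a `circuit_network` from [build_network()].
#' @param n_cycles,steps_per_cycle overrides of the configured values.
#' @param theta implicitness of the time scheme (0.5 = trapezoidal).
#' @param jac_every chord-Newton Jacobian refresh interval (steps).
#' @param init named list of initial-state overrides (`V` length-4 volumes in
#'   mL, `P_ao`, `Pc_sys`, `P_ven`, `Pc_pul` in dyn/cm2).
#' @return An object of class `zerod_result`: list with `time` (s, one
#'   cycle), `pressures` (matrix, dyn/cm2: aortic root + each segment distal
#'   node), `flows` (matrix, cm3/s per segment), `chamber_volumes`,
#'   `chamber_pressures`, `outlet_flows` (BC inflow per coronary outlet),
#'   `outlet_pressures`, `mean_outlet_flows`, `convergence` and bookkeeping.
#' @export
simulate_zerod <- function(net, n_cycles = NULL, steps_per_cycle = NULL,
                           theta = 0.5, jac_every = 40, init = list()) {
  stopifnot(inherits(net, "circuit_network"))
  cfg <- net$config
  n_cycles <- n_cycles %||% cfg$n_cycles
  spc <- steps_per_cycle %||% cfg$steps_per_cycle
  period <- cfg$cardiac_period
  dt <- period / spc

  seg <- net$segments
  n <- nrow(seg)
  bc <- net$coronary_bc
  m <- nrow(bc)
  parent <- net$parent
  is_root <- parent == 0
  out_seg <- bc$seg

  iQ <- 1:n; iP <- n + 1:n; iV <- 2 * n + 1:4; iG <- 2 * n + 4 + 1:4
  iPa <- 2 * n + 8 + 1:m; iU <- 2 * n + 8 + m + 1:m
  nst <- 2 * n + 8 + 2 * m

  # child-flow aggregation matrix: (A %*% Q)[s] = sum of flows of children of s
  A <- matrix(0, n, n)
  for (s in seq_len(n)) if (!is_root[s]) A[parent[s], s] <- 1

  ch <- net$chambers       # LA, LV, RA, RV
  awk <- net$aortic_bc; pwk <- net$pulmonary_bc
  Ropen <- cfg$valve_R_open; Rclosed <- cfg$valve_R_closed; vk <- cfg$valve_k
  valve <- function(dp) {
    s <- stats::plogis(vk * dp)
    dp * (s / Ropen + (1 - s) / Rclosed)
  }
  pim_lv <- bc$pim_source == "LV"

  rhs <- function(t, y) {
    Q <- y[iQ]; P <- y[iP]; V <- y[iV]
    P_ao <- y[iG[1]]; Pc_sys <- y[iG[2]]; P_ven <- y[iG[3]]; Pc_pul <- y[iG[4]]
    Pa <- y[iPa]; U <- y[iU]

    P_LA <- chamber_pressure(ch$LA, V[1], t, period)
    P_LV <- chamber_pressure(ch$LV, V[2], t, period)
    P_RA <- chamber_pressure(ch$RA, V[3], t, period)
    P_RV <- chamber_pressure(ch$RV, V[4], t, period)

    Pprox <- ifelse(is_root, P_ao, P[pmax(parent, 1L)])
    dQ <- (Pprox - P - seg$R * Q - seg$S * abs(Q) * Q) / seg$L

    Pim <- bc$pim_scale * ifelse(pim_lv, P_LV, P_RV)
    Pimn <- U + Pim
    q_ra <- (P[out_seg] - Pa) / bc$Ra
    q_ram <- (Pa - Pimn) / bc$Ramicro
    q_rv <- (Pimn - P_ven) / bc$Rv

    drain <- drop(A %*% Q)
    drain[out_seg] <- q_ra
    dP <- (Q - drain) / seg$C

    dPa <- (q_ra - q_ram) / bc$Ca
    dU <- (q_ram - q_rv) / bc$Cim

    Qmv <- valve(P_LA - P_LV)
    Qav <- valve(P_LV - P_ao)
    Qtr <- valve(P_RA - P_RV)
    Qpv <- valve(P_RV - Pc_pul)          # pulmonary Rp folded into open valve
    Qsys <- (P_ao - Pc_sys) / awk$Rp
    Qsysd <- (Pc_sys - P_ven) / awk$Rd
    Qra_in <- (P_ven - P_RA) / cfg$R_ven
    Qpul_ven <- (Pc_pul - P_LA) / pwk$Rd

    dV <- c(Qpul_ven - Qmv, Qmv - Qav, Qra_in - Qtr, Qtr - Qpv)
    dG <- c((Qav - Qsys - sum(Q[is_root])) / cfg$C_ao,
            (Qsys - Qsysd) / awk$C,
            (Qsysd + sum(q_rv) - Qra_in) / cfg$C_ven,
            (Qpv - Qpul_ven) / pwk$C)

    out <- numeric(nst)
    out[iQ] <- dQ; out[iP] <- dP; out[iV] <- dV; out[iG] <- dG
    out[iPa] <- dPa; out[iU] <- dU
    out
  }

  # ---- initial state: steady solve at the configured mean aortic pressure
  init <- utils::modifyList(cfg$init, init)
  p0 <- init$P_ao %||% cfg$p_inlet_steady
  st <- steady_flow_split(net, p_inlet = p0, p_venous = cfg$p_venous_steady)
  y <- numeric(nst)
  y[iQ] <- st$segment_flows
  y[iP] <- st$node_pressures
  y[iV] <- init$V %||% c(60, 130, 60, 130)
  y[iG] <- c(p0, init$Pc_sys %||% (0.97 * p0),
             init$P_ven %||% cfg$p_venous_steady,
             init$Pc_pul %||% mmHg_to_dyncm2(15))
  q_out0 <- st$segment_flows[out_seg]
  y[iPa] <- st$node_pressures[out_seg] - bc$Ra * q_out0
  y[iU] <- y[iPa] - bc$Ramicro * q_out0   # Pim(0) ~ 0 at diastolic elastance

  # ---- time stepping (chord Newton, theta scheme)
  atol <- cfg$atol; rtol <- cfg$rtol
  Jinv <- NULL; steps_since_jac <- Inf
  refresh <- function(t, y, f) {
    J <- diag(nst) - dt * theta * fd_jacobian(rhs, t, y, f)
    solve(J)
  }

  nt_total <- n_cycles * spc
  cyc_mean_pao <- numeric(n_cycles)
  cyc_mean_qout <- matrix(0, n_cycles, m)
  rec_t <- numeric(spc); rec_y <- matrix(NA_real_, spc, nst)
  acc_pao <- 0; acc_qout <- numeric(m)

  t <- 0
  for (k in seq_len(nt_total)) {
    f0 <- rhs(t, y)
    t1 <- t + dt
    y1 <- y + dt * f0
    converged <- FALSE
    for (att in 1:2) {
      if (steps_since_jac >= jac_every || is.null(Jinv)) {
        Jinv <- refresh(t1, y1, rhs(t1, y1))
        steps_since_jac <- 0
      }
      for (it in 1:12) {
        f1 <- rhs(t1, y1)
        if (!all(is.finite(f1)))
          stop("solver error: non-finite state at step ", k, " (t = ",
               signif(t1, 6), " s)")
        g <- y1 - y - dt * ((1 - theta) * f0 + theta * f1)
        dy <- -drop(Jinv %*% g)
        y1 <- y1 + dy
        if (max(abs(dy) / (atol + rtol * abs(y1))) < 1) { converged <- TRUE; break }
      }
      if (converged) break
      Jinv <- NULL   # retry once with a fresh Jacobian
    }
    if (!converged)
      stop("solver error: Newton failed at step ", k, " (t = ",
           signif(t1, 6), " s)")
    steps_since_jac <- steps_since_jac + 1
    y <- y1; t <- t1

    cyc <- ceiling(k / spc)
    q_bc <- (y[iP][out_seg] - y[iPa]) / bc$Ra
    acc_pao <- acc_pao + y[iG[1]]
    acc_qout <- acc_qout + q_bc
    if (k %% spc == 0) {
      cyc_mean_pao[cyc] <- acc_pao / spc
      cyc_mean_qout[cyc, ] <- acc_qout / spc
      acc_pao <- 0; acc_qout <- numeric(m)
    }
    if (cyc == n_cycles) {
      j <- k - (n_cycles - 1) * spc
      rec_t[j] <- t; rec_y[j, ] <- y
    }
  }

  conv <- if (n_cycles >= 2) {
    max(abs(cyc_mean_pao[n_cycles] - cyc_mean_pao[n_cycles - 1]) /
          abs(cyc_mean_pao[n_cycles]),
        abs(cyc_mean_qout[n_cycles, ] - cyc_mean_qout[n_cycles - 1, ]) /
          pmax(abs(cyc_mean_qout[n_cycles, ]), 1e-9))
  } else NA_real_
  if (is.finite(conv) && conv > 0.01)
    warning("cycle-to-cycle change ", signif(100 * conv, 3),
            "% > 1%: periodic state may not be reached")

  tloc <- rec_t - (n_cycles - 1) * period
  chV <- rec_y[, iV, drop = FALSE]
  colnames(chV) <- c("LA", "LV", "RA", "RV")
  chP <- sapply(seq_along(ch), function(i)
    chamber_pressure(ch[[i]], chV[, i], tloc, period))
  colnames(chP) <- names(ch)

  pressures <- cbind(aorta = rec_y[, iG[1]], rec_y[, iP, drop = FALSE])
  colnames(pressures) <- c("aorta", as.character(seg$id))
  flows <- rec_y[, iQ, drop = FALSE]
  colnames(flows) <- as.character(seg$id)
  q_out <- (rec_y[, iP, drop = FALSE][, out_seg, drop = FALSE] -
              rec_y[, iPa, drop = FALSE]) / rep(bc$Ra, each = spc)
  colnames(q_out) <- as.character(bc$outlet_id)

  structure(list(
    time = tloc,
    period = period, steps_per_cycle = spc, n_cycles = n_cycles,
    pressures = pressures, flows = flows,
    chamber_volumes = chV, chamber_pressures = chP,
    outlet_flows = q_out,
    outlet_pressures = rec_y[, iPa, drop = FALSE],
    mean_outlet_flows = stats::setNames(colMeans(q_out),
                                        as.character(bc$outlet_id)),
    mean_aortic_pressure = mean(rec_y[, iG[1]]),
    cycle_means = list(aortic_pressure = cyc_mean_pao,
                       outlet_flows = cyc_mean_qout),
    convergence = conv,
    network = net
  ), class = "zerod_result")
}

#' @export
print.zerod_result <- function(x, ...) {
  cat("<zerod_result> final cycle of ", x$n_cycles, " (",
      x$steps_per_cycle, " steps); mean aortic pressure ",
      signif(dyncm2_to_mmHg(x$mean_aortic_pressure), 4), " mmHg; ",
      "total coronary flow ",
      signif(cm3s_to_mlmin(sum(x$mean_outlet_flows)), 4), " mL/min; ",
      "cycle-to-cycle change ", signif(100 * x$convergence, 3), "%\n", sep = "")
  invisible(x)
}

#' Export a simulation result to CSV
#'
#' Long format: time (s), node, pressure_mmHg, flow_mL_per_s (flow of the
#' segment whose distal node is `node`; NA for the aortic root).
#'
#' @param result a `zerod_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
result_to_csv <- function(result, path) {
  nodes <- colnames(result$pressures)
  df <- do.call(rbind, lapply(seq_along(nodes), function(j) {
    data.frame(time = result$time, node = nodes[j],
               pressure_mmHg = dyncm2_to_mmHg(result$pressures[, j]),
               flow_mL_per_s = if (nodes[j] == "aorta") NA_real_ else
                 result$flows[, nodes[j]])
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
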