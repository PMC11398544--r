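# Steady resistor-network surrogate.
#
# For quasi-steady flow-split estimation (the inner model of the Bayesian
# personalization and of the FFR/mean-flow surrogates) the capacitors carry
# no net cycle-mean current and the inductors no mean pressure drop, so the
# network reduces to resistors plus the quadratic stenosis elements. The
# nonlinear system is solved by a fixed point on the stenosis-linearized
# resistance R_eff = R + S |Q|, each pass being an exact series/parallel
# tree reduction.

#' Steady flow-split solution of the coronary tree
#'
#' Solves the resistor network formed by the coronary tree segments (R plus
#' stenosis S|Q|Q losses) and the total distal resistance of each outlet
#' boundary condition, driven by a constant inlet (aortic) and venous
#' pressure.
#'
#' @param net a `circuit_network`.
#' @param r_outlets optional replacement of the total distal resistance for a
#'   subset of outlets (named vector of outlet ids, or vector over the
#'   LV-perfusing outlets in tree order); see [set_outlet_resistances()].
#' @param p_inlet,p_venous driving pressures (dyn/cm2); defaults from the
#'   network configuration.
#' @param tol relative fixed-point tolerance on segment flows.
#' @param max_iter fixed-point iteration cap.
#' @return A list of class `steady_result` with elements `outlet_flows`
#'   (named, cm3/s), `segment_flows`, `node_pressures` (pressure at the
#'   distal node of each segment, dyn/cm2), `p_inlet`, and `iterations`.
#' @export
steady_flow_split <- function(net, r_outlets = NULL,
                              p_inlet = NULL, p_venous = NULL,
                              tol = 1e-12, max_iter = 50) {
  stopifnot(inherits(net, "circuit_network"))
  if (!is.null(r_outlets)) net <- set_outlet_resistances(net, r_outlets)
  p_in <- p_inlet %||% net$config$p_inlet_steady
  p_v <- p_venous %||% net$config$p_venous_steady

  seg <- net$segments
  n <- nrow(seg)
  ord <- net$order
  rev_ord <- rev(ord)
  parent <- net$parent
  r_bc <- rep(NA_real_, n)
  r_bc[net$coronary_bc$seg] <- net$coronary_bc$Ra + net$coronary_bc$Ramicro +
    net$coronary_bc$Rv

  Q <- rep(0, n)
  Req <- numeric(n)
  for (it in seq_len(max_iter)) {
    Reff <- seg$R + seg$S * abs(Q)
    # bottom-up equivalent resistance (path to venous node)
    for (s in rev_ord) {
      if (seg$outlet[s]) {
        Req[s] <- Reff[s] + r_bc[s]
      } else {
        kids <- which(parent == s)
        Req[s] <- Reff[s] + 1 / sum(1 / Req[kids])
      }
    }
    # top-down pressures and flows
    Qn <- numeric(n); Pd <- numeric(n)
    for (s in ord) {
      pp <- if (parent[s] == 0) p_in else Pd[parent[s]]
      Qn[s] <- (pp - p_v) / Req[s]
      Pd[s] <- pp - Reff[s] * Qn[s]
    }
    delta <- max(abs(Qn - Q) / pmax(abs(Qn), 1e-12))
    Q <- Qn
    if (delta < tol) break
  }

  out <- net$coronary_bc$seg
  structure(list(
    outlet_flows = stats::setNames(Q[out], net$coronary_bc$outlet_id),
    segment_flows = stats::setNames(Q, seg$id),
    node_pressures = stats::setNames(Pd, seg$id),
    p_inlet = p_in, p_venous = p_v,
    iterations = it, network = net
  ), class = "steady_result")
}

#' Flows at the LV-perfusing outlets for a resistance vector
#'
#' The map f(r) used inside the Bayesian personalization: given the distal
#' resistances `r` of the LV-perfusing outlets (other outlets keep their
#' Murray-law values), returns the simulated steady flows at those outlets in
#' mL/min.
#'
#' @param net a `circuit_network` (typically already under hyperemia).
#' @param r distal resistances of the LV-perfusing outlets, in the order of
#'   [lv_outlet_ids()].
#' @param ... passed to [steady_flow_split()].
#' @return Named vector of outlet flows (mL/min).
#' @export
lv_outlet_flows <- function(net, r, ...) {
  ids <- as.character(lv_outlet_ids(net))
  res <- steady_flow_split(net, r_outlets = stats::setNames(r, ids), ...)
  cm3s_to_mlmin(res$outlet_flows[ids])
}

#' Ids of the LV-perfusing outlets, in tree order
#'
#' @param net a `circuit_network`.
#' @return Character/integer vector of outlet ids.
#' @export
lv_outlet_ids <- function(net) {
  bc <- net$coronary_bc
  bc$outlet_id[net$segments$perfuses_LV[bc$seg]]
}
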