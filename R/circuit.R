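# Lumped-parameter (0D) closed-loop circulation model: network construction.
#
# The circuit analogy: resistors model viscous losses, capacitors vessel
# compliance, inductors blood inertia. Each anatomical branch (a length of
# artery separated by bifurcations) maps to one vessel segment carrying
# series R and L, a junction capacitance C at its distal node, and a
# nonlinear stenosis coefficient S with pressure loss S*|Q|*Q.

#' Poiseuille resistance of a vessel segment
#'
#' R = 128 mu l / (pi d^4), the fully developed laminar-flow value.
#'
#' @param length segment length (cm).
#' @param diameter lumen diameter (cm).
#' @param viscosity dynamic viscosity (poise); default whole blood.
#' @return Resistance in dyn.s/cm5.
#' @export
poiseuille_resistance <- function(length, diameter, viscosity = 0.04) {
  128 * viscosity * length / (pi * diameter^4)
}

#' Inertance of a vessel segment
#'
#' L = 4 rho l / (pi d^2).
#'
#' @param length segment length (cm).
#' @param diameter lumen diameter (cm).
#' @param density blood density (g/cm3).
#' @return Inductance in dyn.s2/cm5.
#' @export
vessel_inductance <- function(length, diameter, density = 1.06) {
  4 * density * length / (pi * diameter^2)
}

#' Compliance of a vessel segment
#'
#' Thin-walled linear compliance per unit length,
#' C = 3 pi r^2 l / (2 (Eh/r)), with the stiffness ratio Eh/r taken from the
#' standard empirical fit Eh/r = k1 exp(k2 r) + k3 (k1 = 2e7 dyn/cm2,
#' k2 = -22.53 1/cm, k3 = 8.65e5 dyn/cm2). Monotone in both length and
#' diameter; overridable through [network_config()].
#'
#' @param length segment length (cm).
#' @param diameter lumen diameter (cm).
#' @param k1,k2,k3 stiffness-fit constants.
#' @return Capacitance in cm5/dyn.
#' @export
vessel_compliance <- function(length, diameter,
                              k1 = 2e7, k2 = -22.53, k3 = 8.65e5) {
  r <- diameter / 2
  stiff <- k1 * exp(k2 * r) + k3
  3 * pi * r^2 * length / (2 * stiff)
}

#' Stenosis coefficient from severity
#'
#' Expansion-loss coefficient for the quadratic stenosis pressure drop
#' dP = S |Q| Q: S = Kt rho / (2 A0^2) * (A0/As - 1)^2 where As is the
#' stenotic lumen area, As = A0 (1 - severity). Severity is the fractional
#' area reduction in [0, 1); severity 0 gives S = 0.
#'
#' @param diameter reference (healthy) lumen diameter (cm).
#' @param severity fractional area reduction in [0, 1).
#' @param density blood density (g/cm3).
#' @param kt empirical turbulent-loss constant.
#' @return Stenosis coefficient in dyn.s2/cm8.
#' @export
stenosis_coefficient <- function(diameter, severity, density = 1.06, kt = 1.52) {
  stopifnot(all(severity >= 0), all(severity < 1))
  a0 <- pi * diameter^2 / 4
  kt * density / (2 * a0^2) * (1 / (1 - severity) - 1)^2
}

#' Stenosis pressure loss
#'
#' dP = S |Q| Q. Odd in Q: the loss always opposes the flow direction.
#'
#' @param S stenosis coefficient (dyn.s2/cm8), S >= 0.
#' @param Q flow (cm3/s).
#' @return Pressure loss (dyn/cm2), same sign as Q.
#' @export
stenosis_pressure_loss <- function(S, Q) {
  stopifnot(all(S >= 0))
  S * abs(Q) * Q
}

#' Heart chamber specification (time-varying elastance)
#'
#' Chamber pressure is P = E(t) (V - V0), with E(t) interpolating between
#' elastance_min and elastance_max over an activation window via a smooth
#' raised-cosine bump (configurable through `activation_fun`).
#'
#' @param elastance_max,elastance_min maximal/minimal elastance (dyn/cm2 per
#'   cm3). Must satisfy elastance_max >= elastance_min > 0.
#' @param activation_onset onset of activation as a fraction of the cardiac
#'   period in [0, 1).
#' @param activation_duration duration of activation as a fraction of the
#'   period in [0, 1].
#' @param unstressed_volume V0 (mL).
#' @param activation_fun function mapping normalized phase s in [0,1] to
#'   activation in [0,1]; default 0.5 (1 - cos(2 pi s)).
#' @return An object of class `heart_chamber`.
#' @export
heart_chamber <- function(elastance_max, elastance_min,
                          activation_onset = 0, activation_duration = 0.35,
                          unstressed_volume = 5,
                          activation_fun = NULL) {
  stopifnot(elastance_max >= elastance_min, elastance_min > 0,
            activation_duration >= 0, activation_duration <= 1)
  structure(list(
    elastance_max = elastance_max,
    elastance_min = elastance_min,
    activation_onset = activation_onset,
    activation_duration = activation_duration,
    unstressed_volume = unstressed_volume,
    activation_fun = activation_fun %||% function(s) 0.5 * (1 - cos(2 * pi * s))
  ), class = "heart_chamber")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Elastance of a chamber at time t
#'
#' @param chamber a [heart_chamber()].
#' @param t time (s); reduced modulo the cardiac period.
#' @param period cardiac period T (s).
#' @return Elastance (dyn/cm2 per cm3).
#' @export
elastance_at <- function(chamber, t, period) {
  phase <- (t / period - chamber$activation_onset) %% 1
  s <- phase / max(chamber$activation_duration, .Machine$double.eps)
  act <- ifelse(s >= 0 & s <= 1, chamber$activation_fun(pmin(pmax(s, 0), 1)), 0)
  chamber$elastance_min + (chamber$elastance_max - chamber$elastance_min) * act
}

#' Chamber pressure from the elastance model
#'
#' P = E(t) (V - V0). Volumes below V0 yield non-positive pressures; this is
#' permitted (suction is physical in early diastole).
#'
#' @inheritParams elastance_at
#' @param volume chamber volume (mL).
#' @return Pressure (dyn/cm2).
#' @export
chamber_pressure <- function(chamber, volume, t, period) {
  elastance_at(chamber, t, period) * (volume - chamber$unstressed_volume)
}

#' Windkessel (RCR) boundary condition
#'
#' @param Rp,Rd proximal and distal resistance (dyn.s/cm5).
#' @param C compliance (cm5/dyn).
#' @param Pref reference (distal) pressure (dyn/cm2).
#' @return An object of class `windkessel_bc`.
#' @export
windkessel_bc <- function(Rp, C, Rd, Pref = 0) {
  stopifnot(Rp >= 0, C >= 0, Rd >= 0)
  structure(list(Rp = Rp, C = C, Rd = Rd, Pref = Pref), class = "windkessel_bc")
}

#' Split a total resistance among outlets by Murray's law
#'
#' Outlet conductances are proportional to diameter^exponent and the parallel
#' combination of the returned resistances equals `total_R`.
#'
#' @param total_R total (parallel) resistance (dyn.s/cm5), > 0.
#' @param diameters outlet diameters (cm), all > 0.
#' @param exponent Murray exponent; 2.6 for coronary arteries.
#' @return Vector of per-outlet resistances.
#' @export
murray_resistance_split <- function(total_R, diameters, exponent = 2.6) {
  if (length(diameters) == 0) stop("empty diameter list")
  stopifnot(total_R > 0, all(diameters > 0))
  g <- diameters^exponent
  g <- g / sum(g) / total_R    # conductances, sum = 1/total_R
  1 / g
}

#' Default configuration of the closed-loop 0D model
#'
#' All element values not derivable from the anatomy are physiologic
#' placeholders (the stage-1 systemic calibration of a real patient model is
#' not part of this package's scope) and every one of them is overridable.
#' Pressures in the configuration are accepted in mmHg for readability and
#' converted internally.
#'
#' @param cardiac_period cardiac period T (s).
#' @param n_cycles number of cycles to integrate (final cycle retained).
#' @param steps_per_cycle time steps per cycle.
#' @param blood_density g/cm3.
#' @param blood_viscosity poise.
#' @param resistance_fun,compliance_fun,inductance_fun callbacks
#'   (length, diameter) -> element value; defaults are
#'   [poiseuille_resistance()], [vessel_compliance()], [vessel_inductance()].
#' @param total_coronary_resistance total resting coronary distal resistance
#'   (dyn.s/cm5), split among outlets by Murray's law.
#' @param coronary_split fractions of each outlet's total distal resistance
#'   assigned to Ra, Ramicro, Rv (must sum to 1).
#' @param Ca,Cim per-outlet proximal and intramyocardial capacitance (cm5/dyn).
#' @param pim_scale_lv,pim_scale_rv intramyocardial pressure as a fraction of
#'   the source chamber (LV for LV-perfusing outlets, RV otherwise).
#' @param murray_exponent exponent for the diameter-based resistance split.
#' @param hyperemia_factor multiplier on distal coronary resistances under
#'   hyperemia (adenosine stress); 0.24 by default.
#' @param p_inlet_steady,p_venous_steady inlet/venous pressures (mmHg) used by
#'   the steady flow-split surrogate.
#' @param chambers named list of four [heart_chamber()] objects
#'   (LA, LV, RA, RV).
#' @param aortic_bc systemic [windkessel_bc()].
#' @param pulmonary_bc pulmonary [windkessel_bc()].
#' @param C_ao aortic-root capacitance (cm5/dyn).
#' @param C_ven,R_ven venous capacitance and resistance.
#' @param valve_R_open,valve_R_closed,valve_k smoothed diode valve parameters.
#' @param init initial state overrides (named list; see [simulate_zerod()]).
#' @param atol,rtol Newton tolerances of the implicit integrator.
#' @param ... additional overrides stored verbatim.
#' @return A list of class `network_config`.
#' @export
network_config <- function(cardiac_period = 0.8,
                           n_cycles = 5,
                           steps_per_cycle = 1000,
                           blood_density = 1.06,
                           blood_viscosity = 0.04,
                           resistance_fun = NULL,
                           compliance_fun = NULL,
                           inductance_fun = NULL,
                           total_coronary_resistance = 36000,
                           coronary_split = c(Ra = 0.32, Ramicro = 0.52, Rv = 0.16),
                           Ca = 1e-6, Cim = 1e-5,
                           pim_scale_lv = 1.0, pim_scale_rv = 0.5,
                           murray_exponent = 2.6,
                           hyperemia_factor = 0.24,
                           p_inlet_steady = 90, p_venous_steady = 5,
                           chambers = NULL,
                           aortic_bc = NULL,
                           pulmonary_bc = NULL,
                           C_ao = 3e-4,
                           C_ven = 0.015, R_ven = 30,
                           valve_R_open = 5, valve_R_closed = 1e8,
                           valve_k = 0.01,
                           init = list(),
                           atol = 1e-8, rtol = 1e-6,
                           ...) {
  mu <- blood_viscosity; rho <- blood_density
  stopifnot(abs(sum(coronary_split) - 1) < 1e-12, n_cycles >= 1)
  e <- MMHG_TO_DYNCM2  # elastances below given in mmHg/mL
  cfg <- list(
    cardiac_period = cardiac_period, n_cycles = n_cycles,
    steps_per_cycle = steps_per_cycle,
    blood_density = rho, blood_viscosity = mu,
    resistance_fun = resistance_fun %||%
      function(l, d) poiseuille_resistance(l, d, mu),
    compliance_fun = compliance_fun %||% vessel_compliance,
    inductance_fun = inductance_fun %||%
      function(l, d) vessel_inductance(l, d, rho),
    total_coronary_resistance = total_coronary_resistance,
    coronary_split = coronary_split, Ca = Ca, Cim = Cim,
    pim_scale_lv = pim_scale_lv, pim_scale_rv = pim_scale_rv,
    murray_exponent = murray_exponent,
    hyperemia_factor = hyperemia_factor,
    p_inlet_steady = mmHg_to_dyncm2(p_inlet_steady),
    p_venous_steady = mmHg_to_dyncm2(p_venous_steady),
    chambers = chambers %||% list(
      LA = heart_chamber(0.28 * e, 0.16 * e, activation_onset = 0.85,
                         activation_duration = 0.13, unstressed_volume = 3),
      LV = heart_chamber(2.6 * e, 0.055 * e, activation_onset = 0,
                         activation_duration = 0.38, unstressed_volume = 10),
      RA = heart_chamber(0.18 * e, 0.12 * e, activation_onset = 0.85,
                         activation_duration = 0.13, unstressed_volume = 3),
      RV = heart_chamber(0.7 * e, 0.045 * e, activation_onset = 0,
                         activation_duration = 0.38, unstressed_volume = 10)
    ),
    aortic_bc = aortic_bc %||% windkessel_bc(Rp = 90, C = 1.3e-3, Rd = 1350),
    pulmonary_bc = pulmonary_bc %||% windkessel_bc(Rp = 40, C = 4e-3, Rd = 60),
    C_ao = C_ao, C_ven = C_ven, R_ven = R_ven,
    valve_R_open = valve_R_open, valve_R_closed = valve_R_closed,
    valve_k = valve_k,
    init = init, atol = atol, rtol = rtol
  )
  extra <- list(...)
  cfg[names(extra)] <- extra
  class(cfg) <- "network_config"
  cfg
}

#' Read / write the coronary-tree text format
#'
#' Delimited text with columns {branch_id, parent_id, length_cm, diameter_cm,
#' stenosis_severity, outlet_flag, perfuses_LV_flag, outlet_x, outlet_y,
#' outlet_z}. `parent_id = 0` denotes a root branch attached to the aortic
#' root.
#'
#' @param path file path.
#' @return A data.frame (the tree description).
#' @export
read_coronary_tree <- function(path) {
  tree <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_tree(tree)
  tree
}

#' @rdname read_coronary_tree
#' @param tree tree data.frame.
#' @export
write_coronary_tree <- function(tree, path) {
  utils::write.csv(tree, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_tree <- function(tree) {
  req <- c("branch_id", "parent_id", "length_cm", "diameter_cm",
           "stenosis_severity", "outlet_flag", "perfuses_LV_flag",
           "outlet_x", "outlet_y", "outlet_z")
  missing <- setdiff(req, names(tree))
  if (length(missing))
    stop("tree description missing columns: ", paste(missing, collapse = ", "))
  if (any(tree$length_cm <= 0) || any(tree$diameter_cm <= 0))
    stop("nonpositive branch geometry")
  # connectivity: every branch must reach a root through parent links
  id2row <- match(tree$parent_id, tree$branch_id)
  for (i in seq_len(nrow(tree))) {
    j <- i; seen <- 0
    while (tree$parent_id[j] != 0) {
      j <- id2row[j]
      if (is.na(j)) stop("branch ", tree$branch_id[i], " has unknown parent")
      seen <- seen + 1
      if (seen > nrow(tree)) stop("tree contains a cycle: disconnected from root")
    }
  }
  invisible(tree)
}

#' Build a closed-loop circuit network from a coronary-tree description
#'
#' Maps each anatomical branch to one vessel segment with R, C, L from the
#' configured geometry formulas and a stenosis coefficient S > 0 for stenosed
#' branches; attaches a coronary outlet boundary condition (Ra, Ca, Ramicro,
#' Cim with intramyocardial pressure, Rv) to every outlet, splitting the total
#' coronary distal resistance among outlets by Murray's law; and wires the
#' tree into the closed-loop systemic/pulmonary circulation.
#'
#' @param tree coronary-tree description (see [read_coronary_tree()]).
#' @param config a [network_config()].
#' @return An object of class `circuit_network`.
#' @export
build_network <- function(tree, config = network_config()) {
  validate_tree(tree)
  n <- nrow(tree)
  parent <- match(tree$parent_id, tree$branch_id)
  parent[tree$parent_id == 0] <- 0L
  parent <- as.integer(parent)

  seg <- data.frame(
    id = tree$branch_id,
    parent = parent,
    length = tree$length_cm,
    diameter = tree$diameter_cm,
    R = config$resistance_fun(tree$length_cm, tree$diameter_cm),
    C = config$compliance_fun(tree$length_cm, tree$diameter_cm),
    L = config$inductance_fun(tree$length_cm, tree$diameter_cm),
    S = ifelse(tree$stenosis_severity > 0,
               stenosis_coefficient(tree$diameter_cm, tree$stenosis_severity,
                                    config$blood_density),
               0),
    severity = tree$stenosis_severity,
    outlet = as.logical(tree$outlet_flag),
    perfuses_LV = as.logical(tree$perfuses_LV_flag),
    stringsAsFactors = FALSE
  )

  # leaves must be outlets, internal segments must not be
  has_child <- seq_len(n) %in% parent
  if (any(seg$outlet & has_child))
    stop("outlet branches cannot have children")
  if (any(!seg$outlet & !has_child))
    stop("terminal branches must be flagged as outlets")

  # topological order (parents before children)
  ord <- integer(0); placed <- rep(FALSE, n)
  while (length(ord) < n) {
    ready <- which(!placed & (parent == 0 | placed[pmax(parent, 1)]))
    if (!length(ready)) stop("disconnected tree")
    ord <- c(ord, ready); placed[ready] <- TRUE
  }

  out_idx <- which(seg$outlet)
  r_out <- murray_resistance_split(config$total_coronary_resistance,
                                   seg$diameter[out_idx],
                                   config$murray_exponent)
  sp <- config$coronary_split
  cor_bc <- data.frame(
    seg = out_idx,
    outlet_id = seg$id[out_idx],
    Ra = r_out * sp[["Ra"]],
    Ramicro = r_out * sp[["Ramicro"]],
    Rv = r_out * sp[["Rv"]],
    Ca = rep(config$Ca, length(out_idx)),
    Cim = rep(config$Cim, length(out_idx)),
    pim_source = ifelse(seg$perfuses_LV[out_idx], "LV", "RV"),
    pim_scale = ifelse(seg$perfuses_LV[out_idx],
                       config$pim_scale_lv, config$pim_scale_rv),
    stringsAsFactors = FALSE
  )

  net <- list(segments = seg, order = ord, parent = parent,
              coronary_bc = cor_bc,
              chambers = config$chambers,
              aortic_bc = config$aortic_bc,
              pulmonary_bc = config$pulmonary_bc,
              config = config,
              tree = tree)
  class(net) <- "circuit_network"
  net
}

#' @export
print.circuit_network <- function(x, ...) {
  cat("<circuit_network> ", nrow(x$segments), " segments, ",
      nrow(x$coronary_bc), " coronary outlets (",
      sum(x$segments$perfuses_LV[x$segments$outlet]), " perfusing the LV), ",
      sum(x$segments$S > 0), " stenosed\n", sep = "")
  invisible(x)
}

#' Apply hyperemic scaling to the coronary boundary conditions
#'
#' Multiplies Ra, Ramicro and Rv of every coronary outlet boundary condition
#' by `factor` (0.24 reproduces maximal adenosine vasodilation relative to
#' rest). All other parameters are unchanged.
#'
#' @param net a `circuit_network`.
#' @param factor positive scaling factor.
#' @return The modified network.
#' @export
apply_hyperemia <- function(net, factor = 0.24) {
  stopifnot(inherits(net, "circuit_network"), factor > 0)
  net$coronary_bc$Ra <- net$coronary_bc$Ra * factor
  net$coronary_bc$Ramicro <- net$coronary_bc$Ramicro * factor
  net$coronary_bc$Rv <- net$coronary_bc$Rv * factor
  net
}

#' Total distal resistance of each coronary outlet
#'
#' @param net a `circuit_network`.
#' @return Named vector Ra + Ramicro + Rv per outlet.
#' @export
outlet_resistances <- function(net) {
  bc <- net$coronary_bc
  stats::setNames(bc$Ra + bc$Ramicro + bc$Rv, bc$outlet_id)
}

#' Replace the distal resistances of selected coronary outlets
#'
#' The per-outlet split among Ra, Ramicro and Rv is preserved.
#'
#' @param net a `circuit_network`.
#' @param r named or positional vector of new total distal resistances.
#' @param outlet_ids outlets to modify (default: ids of `r`'s names, else all
#'   LV-perfusing outlets).
#' @return The modified network.
#' @export
set_outlet_resistances <- function(net, r, outlet_ids = NULL) {
  bc <- net$coronary_bc
  if (is.null(outlet_ids)) {
    outlet_ids <- if (!is.null(names(r))) names(r) else
      bc$outlet_id[net$segments$perfuses_LV[bc$seg]]
  }
  idx <- match(outlet_ids, bc$outlet_id)
  if (anyNA(idx)) stop("unknown outlet id")
  stopifnot(length(r) == length(idx), all(r > 0))
  tot <- bc$Ra[idx] + bc$Ramicro[idx] + bc$Rv[idx]
  sc <- r / tot
  net$coronary_bc$Ra[idx] <- bc$Ra[idx] * sc
  net$coronary_bc$Ramicro[idx] <- bc$Ramicro[idx] * sc
  net$coronary_bc$Rv[idx] <- bc$Rv[idx] * sc
  net
}
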