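# Clinical and biomechanical quantities of interest.
#
# TAWSS and OSI act on a wall shear waveform over one cardiac cycle; FFR is
# the cycle-mean pressure distal to a lesion over the cycle-mean aortic
# pressure under hyperemia. At the 0D level, wall shear for a branch is
# approximated by the Poiseuille wall value tau = 32 mu Q / (pi d^3) of that
# branch's flow waveform.

trap_quad <- function(y, x) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Time-averaged wall shear stress
#'
#' TAWSS = (1/T) integral |tau| dt over one period, by trapezoidal
#' quadrature. For a vector-valued shear (matrix input, one column per
#' component) |tau| is the Euclidean norm per time point.
#'
#' @param tau shear waveform: numeric vector, or matrix (time x components),
#'   dyn/cm2.
#' @param time strictly increasing time grid spanning one period (s).
#' @return Scalar TAWSS (dyn/cm2).
#' @export
tawss <- function(tau, time) {
  stopifnot(all(diff(time) > 0))
  mag <- if (is.matrix(tau)) sqrt(rowSums(tau^2)) else abs(tau)
  trap_quad(mag, time) / (time[length(time)] - time[1])
}

#' Oscillatory shear index
#'
#' OSI = 1/2 (1 - |integral tau dt| / integral |tau| dt), in [0, 0.5]:
#' 0 for unidirectional shear, 0.5 for perfectly balanced reversal. The
#' numerator uses the magnitude of the (component-wise) time integral.
#'
#' @inheritParams tawss
#' @return Scalar OSI in [0, 0.5]; an identically zero waveform returns 0
#'   with a warning.
#' @export
osi <- function(tau, time) {
  stopifnot(all(diff(time) > 0))
  if (is.matrix(tau)) {
    num <- sqrt(sum(apply(tau, 2, trap_quad, x = time)^2))
    den <- trap_quad(sqrt(rowSums(tau^2)), time)
  } else {
    num <- abs(trap_quad(tau, time))
    den <- trap_quad(abs(tau), time)
  }
  if (den <= 0) {
    warning("identically zero shear waveform; OSI defined as 0")
    return(0)
  }
  min(max(0.5 * (1 - num / den), 0), 0.5)
}

#' Fractional flow reserve from pressure waveforms
#'
#' Cycle-mean pressure distal to the lesion divided by cycle-mean aortic
#' pressure (both under hyperemia). Steady inputs (scalars) are accepted.
#'
#' @param p_distal,p_aortic pressure waveforms on a common time grid (or
#'   scalars), any common unit.
#' @param time optional time grid for non-uniform sampling (plain means are
#'   used when omitted).
#' @return Scalar FFR.
#' @export
ffr <- function(p_distal, p_aortic, time = NULL) {
  stopifnot(length(p_distal) == length(p_aortic))
  m <- function(p) if (is.null(time) || length(p) == 1) mean(p) else
    trap_quad(p, time) / (time[length(time)] - time[1])
  md <- m(p_distal); ma <- m(p_aortic)
  if (ma <= 0) stop("non-positive mean aortic pressure")
  md / ma
}

#' Poiseuille wall shear waveform of a branch
#'
#' tau(t) = 32 mu Q(t) / (pi d^3): the fully developed laminar wall shear
#' used as the 0D-level shear surrogate.
#'
#' @param Q flow waveform (cm3/s).
#' @param diameter branch diameter (cm).
#' @param viscosity poise.
#' @return Shear waveform (dyn/cm2).
#' @export
poiseuille_wall_shear <- function(Q, diameter, viscosity = 0.04) {
  32 * viscosity * Q / (pi * diameter^3)
}

#' Extract a quantity of interest from a 0D result
#'
#' Dispatches on a QoI spec string:
#' \itemize{
#'   \item `"mean_flow:<outlet_id>"` cycle-mean flow of the branch feeding
#'     that outlet (cm3/s; steady results supported);
#'   \item `"ffr:<branch_id>"` pressure at the node distal to the (stenosed)
#'     branch over aortic pressure;
#'   \item `"tawss:<branch_id>"`, `"osi:<branch_id>"` on the branch's
#'     Poiseuille shear waveform (transient results only);
#'   \item a function(result) for user-registered extractors.
#' }
#'
#' @param result a `zerod_result` or `steady_result`.
#' @param qoi_spec spec string or function.
#' @return Scalar QoI.
#' @export
qoi_from_0d <- function(result, qoi_spec) {
  if (is.function(qoi_spec)) return(qoi_spec(result))
  parts <- strsplit(qoi_spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("unknown QoI spec: ", qoi_spec)
  kind <- parts[1]; id <- parts[2]
  steady <- inherits(result, "steady_result")
  net <- result$network
  seg_row <- match(id, as.character(net$segments$id))
  if (is.na(seg_row)) stop("unknown branch/outlet id: ", id)
  switch(kind,
    mean_flow = if (steady) unname(result$segment_flows[id]) else
      mean(result$flows[, id]),
    ffr = if (steady)
      unname(result$node_pressures[id]) / result$p_inlet
    else
      ffr(result$pressures[, id], result$pressures[, "aorta"], result$time),
    tawss = {
      if (steady) stop("tawss requires a transient result")
      tawss(poiseuille_wall_shear(result$flows[, id],
                                  net$segments$diameter[seg_row],
                                  net$config$blood_viscosity), result$time)
    },
    osi = {
      if (steady) stop("osi requires a transient result")
      osi(poiseuille_wall_shear(result$flows[, id],
                                net$segments$diameter[seg_row],
                                net$config$blood_viscosity), result$time)
    },
    stop("unknown QoI spec: ", qoi_spec)
  )
}

#' Draw uncertain model inputs theta = (r, s)
#'
#' r is resampled (with replacement) from the post-burn-in posterior of the
#' outlet resistances; s, a scale factor on the total coronary resistance
#' accounting for the uncertainty in total coronary flow quantification, is
#' independently uniform on `s_range` (the default corresponds to
#' coronary-to-systemic flow fractions of 3-5%).
#'
#' @param posterior a `posterior_samples` (or a draws matrix).
#' @param n number of input vectors.
#' @param seed integer seed.
#' @param s_range support of s.
#' @return Matrix (n x (Nc+1)) with columns r_1..r_Nc, s; class
#'   `uncertain_inputs`.
#' @export
sample_inputs <- function(posterior, n, seed = 1, s_range = c(0.7, 1.25)) {
  R <- if (inherits(posterior, "posterior_samples"))
    posterior_draws(posterior) else as.matrix(posterior)
  with_seed(seed, {
    rows <- sample.int(nrow(R), n, replace = TRUE)
    s <- stats::runif(n, s_range[1], s_range[2])
    out <- cbind(R[rows, , drop = FALSE], s = s)
    colnames(out) <- c(paste0("r_", seq_len(ncol(R))), "s")
    class(out) <- c("uncertain_inputs", class(out))
    out
  })
}

#' Configuration of the high-fidelity surrogate
#'
#' The true high-fidelity model (a 3D finite-element flow solver) is outside
#' this package's scope. Two stand-ins are provided: (a) a table of
#' user-supplied high-fidelity evaluations (theta -> QoI) so real 3D outputs
#' can be plugged in; (b) a synthetic surrogate that evaluates the 0D model
#' (steady or transient) and optionally applies a nonlinear distortion
#' emulating flow physics the 0D model cannot represent. The default
#' `osi_proxy` distortion maps the stenosis-branch mean flow through a
#' non-monotone bump, reproducing the weak or sign-flipped low/high-fidelity
#' correlations seen for oscillatory shear metrics.
#'
#' @param net a `circuit_network` (hyperemic).
#' @param qoi QoI spec string (see [qoi_from_0d()]).
#' @param inner `"steady"` or `"transient"` inner 0D evaluation.
#' @param distortion `"none"` or `"osi_proxy"`.
#' @param distortion_center,distortion_width bump location/width for the
#'   proxy (cm3/s); when a `calibrate_inputs` sample is given they default
#'   to the median and standard deviation of the 0D QoI over that sample
#'   (so the bump straddles the operating range and the correlation with
#'   the monotone low-fidelity predictor collapses); otherwise to the QoI
#'   at the Murray-law reference resistances and 30% of it.
#' @param calibrate_inputs optional `uncertain_inputs` matrix used to
#'   calibrate the proxy (at most 100 rows are evaluated).
#' @param table optional data.frame from [read_hf_table()]; when present,
#'   evaluations are exact lookups and the model is never run.
#' @param n_cycles,steps_per_cycle transient resolution.
#' @return List of class `hf_config`.
#' @export
hf_surrogate_config <- function(net, qoi, inner = c("steady", "transient"),
                                distortion = c("none", "osi_proxy"),
                                distortion_center = NULL,
                                distortion_width = NULL,
                                calibrate_inputs = NULL,
                                table = NULL,
                                n_cycles = 3, steps_per_cycle = 400) {
  inner <- match.arg(inner)
  distortion <- match.arg(distortion)
  cfg <- list(net = net, qoi = qoi, inner = inner, distortion = distortion,
              distortion_center = distortion_center,
              distortion_width = distortion_width, table = table,
              n_cycles = n_cycles, steps_per_cycle = steps_per_cycle)
  if (distortion == "osi_proxy" &&
      (is.null(distortion_center) || is.null(distortion_width))) {
    if (!is.null(calibrate_inputs)) {
      X <- unclass(as.matrix(calibrate_inputs))
      X <- X[seq_len(min(nrow(X), 100)), , drop = FALSE]
      d <- ncol(X) - 1
      qs <- vapply(seq_len(nrow(X)), function(i)
        evaluate_0d_qoi(cfg, X[i, seq_len(d)], X[i, d + 1]), 0)
      cfg$distortion_center <- cfg$distortion_center %||% stats::median(qs)
      cfg$distortion_width <- cfg$distortion_width %||%
        max(stats::sd(qs), 1e-12)
    } else {
      ref <- evaluate_0d_qoi(cfg, outlet_resistances_lv(net), 1)
      cfg$distortion_center <- cfg$distortion_center %||% ref
      cfg$distortion_width <- cfg$distortion_width %||% (0.3 * abs(ref))
    }
  }
  class(cfg) <- "hf_config"
  cfg
}

outlet_resistances_lv <- function(net) {
  r <- outlet_resistances(net)
  r[as.character(lv_outlet_ids(net))]
}

apply_inputs_to_network <- function(net, r, s) {
  # s scales every coronary distal resistance; r then sets the LV outlets
  net <- apply_hyperemia(net, s)   # uniform scale on Ra/Ramicro/Rv
  set_outlet_resistances(net, s * r,
                         outlet_ids = lv_outlet_ids(net))
}

evaluate_0d_qoi <- function(cfg, r, s) {
  net <- apply_inputs_to_network(cfg$net, r, s)
  res <- if (cfg$inner == "steady") steady_flow_split(net) else
    suppressWarnings(simulate_zerod(net, n_cycles = cfg$n_cycles,
                                    steps_per_cycle = cfg$steps_per_cycle))
  qoi_from_0d(res, cfg$qoi)
}

#' Evaluate the high-fidelity surrogate
#'
#' @param inputs an `uncertain_inputs` matrix (rows theta = (r, s)).
#' @param config an [hf_surrogate_config()].
#' @return Numeric vector of QoI values, index-aligned with `inputs`.
#' @export
hf_surrogate <- function(inputs, config) {
  stopifnot(inherits(config, "hf_config"))
  X <- unclass(as.matrix(inputs))
  if (!is.null(config$table)) return(hf_table_lookup(X, config$table))
  d <- ncol(X) - 1
  vapply(seq_len(nrow(X)), function(i) {
    q <- evaluate_0d_qoi(config, X[i, seq_len(d)], X[i, d + 1])
    if (config$distortion == "osi_proxy")
      0.5 * exp(-((q - config$distortion_center) / config$distortion_width)^2)
    else q
  }, 0)
}

#' Read a high-fidelity sample table
#'
#' Delimited text with header `theta_1..theta_d, qoi`, one row per
#' evaluation.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_hf_table <- function(path) {
  tb <- utils::read.csv(path)
  if (!"qoi" %in% names(tb) || !any(grepl("^theta_", names(tb))))
    stop("HF table must have columns theta_1..theta_d and qoi")
  tb
}

hf_table_lookup <- function(X, table, digits = 10) {
  th <- as.matrix(table[, grep("^theta_", names(table)), drop = FALSE])
  if (ncol(th) != ncol(X)) stop("HF table dimension mismatch")
  key <- function(M) apply(signif(M, digits), 1, paste, collapse = "|")
  idx <- match(key(X), key(th))
  if (anyNA(idx)) stop("HF table lookup miss for ", sum(is.na(idx)), " inputs")
  table$qoi[idx]
}
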