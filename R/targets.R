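# LV perfusion territories and branch-specific flow targets.
#
# Each LV point is assigned to its closest LV-perfusing coronary outlet
# (a Voronoi tessellation of the myocardium); branch flow targets are the
# MBF integrals over each territory. Clinical uncertainty is emulated by two
# noise sources: Gaussian perturbation of every point-outlet distance
# (sd = 10% of the deterministic distance; anatomical/registration
# uncertainty) and Gaussian perturbation of the per-point MBF (sd = 20% of
# the baseline value; perfusion-imaging uncertainty). Statistics over many
# realizations yield the target mean vector and its (non-diagonal)
# covariance.

#' Outlets of a coronary tree as an outlet set
#'
#' @param tree a coronary-tree description data.frame.
#' @return data.frame {outlet_id, x, y, z, perfuses_LV} of class `outlet_set`,
#'   with attribute `Nc` = number of LV-perfusing outlets.
#' @export
outlet_set <- function(tree) {
  o <- tree[tree$outlet_flag == 1,
            c("branch_id", "outlet_x", "outlet_y", "outlet_z",
              "perfuses_LV_flag")]
  names(o) <- c("outlet_id", "x", "y", "z", "perfuses_LV")
  o$perfuses_LV <- as.logical(o$perfuses_LV)
  if (!any(o$perfuses_LV)) stop("no LV-perfusing outlet in tree")
  rownames(o) <- NULL
  structure(o, Nc = sum(o$perfuses_LV), class = c("outlet_set", "data.frame"))
}

lv_outlet_coords <- function(outlets) {
  as.matrix(outlets[outlets$perfuses_LV, c("x", "y", "z")])
}

point_outlet_distances <- function(lv, outlets) {
  oc <- lv_outlet_coords(outlets)
  # n_points x Nc Euclidean distances
  d2 <- outer(rowSums(lv$points^2), rep(1, nrow(oc))) +
    outer(rep(1, nrow(lv$points)), rowSums(oc^2)) -
    2 * lv$points %*% t(oc)
  sqrt(pmax(d2, 0))
}

#' Assign LV perfusion territories to coronary outlets
#'
#' Each LV point goes to the LV-perfusing outlet with the minimum (optionally
#' noise-perturbed) distance. With `distance_noise = 0` this is the exact
#' nearest-neighbour (Voronoi) assignment; ties go to the lowest outlet
#' index. Noise is drawn independently per (point, outlet) pair:
#' d_perturbed = d (1 + frac * z), z ~ N(0,1).
#'
#' @param lv an `lv_cloud`.
#' @param outlets an [outlet_set()] (non-LV outlets never receive territory).
#' @param distance_noise noise fraction (sd as a fraction of the
#'   deterministic distance); 0.10 emulates segmentation/registration error.
#' @param seed integer seed (ignored when `distance_noise = 0`).
#' @param distances optional precomputed distance matrix (performance).
#' @return Object of class `territory_assignment`: list with `index`
#'   (per-point outlet index into the LV-perfusing outlets), `outlet_ids`,
#'   `volumes` (cm3 per outlet), `total_volume`.
#' @export
assign_territories <- function(lv, outlets, distance_noise = 0.10, seed = 1,
                               distances = NULL) {
  D <- distances %||% point_outlet_distances(lv, outlets)
  Nc <- ncol(D)
  idx <- if (distance_noise > 0) {
    with_seed(seed, {
      Dp <- D * (1 + distance_noise *
                   matrix(stats::rnorm(length(D)), nrow(D), Nc))
      max.col(-Dp, ties.method = "first")
    })
  } else {
    max.col(-D, ties.method = "first")
  }
  ids <- outlets$outlet_id[outlets$perfuses_LV]
  vols <- numeric(Nc)
  tab <- table(factor(idx, levels = seq_len(Nc)))
  vols <- as.numeric(tab) * lv$voxel_volume
  structure(list(index = idx, outlet_ids = ids,
                 volumes = stats::setNames(vols, ids),
                 total_volume = nrow(lv$points) * lv$voxel_volume),
            class = "territory_assignment")
}

#' Integrate MBF over territories into branch flows
#'
#' flow_k = sum over territory k of mbf_noisy * voxel_volume, with
#' mbf_noisy = mbf (1 + eps), eps ~ N(0, frac^2) i.i.d. per point. With
#' `mbf_noise = 0` the flows sum exactly to the total LV flow.
#'
#' @param lv an `lv_cloud`.
#' @param assignment a [assign_territories()] result covering `lv`.
#' @param mbf_noise noise fraction on per-point MBF (0.20 emulates
#'   perfusion-imaging uncertainty).
#' @param seed integer seed (ignored when `mbf_noise = 0`).
#' @return Named vector of branch flows (mL/min).
#' @export
branch_flows <- function(lv, assignment, mbf_noise = 0.20, seed = 1) {
  stopifnot(length(assignment$index) == length(lv$mbf))
  w <- lv$mbf * lv$voxel_volume
  if (mbf_noise > 0)
    w <- with_seed(seed, w * (1 + mbf_noise * stats::rnorm(length(w))))
  Nc <- length(assignment$outlet_ids)
  f <- numeric(Nc)
  rs <- rowsum(w, assignment$index)
  f[as.integer(rownames(rs))] <- rs
  stats::setNames(f, assignment$outlet_ids)
}

#' Build uncertainty-aware branch flow targets
#'
#' Draws `n_realizations` joint realizations of the territory tessellation
#' (distance noise) and the MBF field (value noise), integrates each into
#' branch flows, and summarizes them as a mean target vector f_CT and a
#' sample covariance Sigma. The covariance is non-diagonal when distance
#' noise is active because adjacent territories exchange points. Sigma is
#' symmetrized and eigenvalue-clipped to positive semi-definiteness.
#'
#' @param lv an `lv_cloud`.
#' @param outlets an [outlet_set()].
#' @param n_realizations number of joint noise realizations (>= 2).
#' @param distance_noise,mbf_noise noise fractions (see
#'   [assign_territories()], [branch_flows()]).
#' @param seed integer master seed.
#' @param keep_realizations store the realization matrix in the result.
#' @return Object of class `flow_target_set`: list with `mean` (mL/min),
#'   `sigma` (mL/min squared), `n_realizations`, `outlet_ids`,
#'   `realizations` (optional), `degenerate` (outlets empty in > 50% of
#'   realizations, with a recorded warning).
#' @export
build_flow_targets <- function(lv, outlets, n_realizations = 2500,
                               distance_noise = 0.10, mbf_noise = 0.20,
                               seed = 1, keep_realizations = TRUE) {
  stopifnot(n_realizations >= 2)
  D <- point_outlet_distances(lv, outlets)
  Nc <- ncol(D)
  n <- nrow(D)
  ids <- outlets$outlet_id[outlets$perfuses_LV]
  w0 <- lv$mbf * lv$voxel_volume

  F <- matrix(0, n_realizations, Nc)
  empty <- numeric(Nc)
  with_seed(seed, {
    for (k in seq_len(n_realizations)) {
      idx <- if (distance_noise > 0) {
        Dp <- D * (1 + distance_noise * matrix(stats::rnorm(n * Nc), n, Nc))
        max.col(-Dp, ties.method = "first")
      } else max.col(-D, ties.method = "first")
      w <- if (mbf_noise > 0) w0 * (1 + mbf_noise * stats::rnorm(n)) else w0
      rs <- rowsum(w, idx)
      row <- numeric(Nc); row[as.integer(rownames(rs))] <- rs
      F[k, ] <- row
      empty <- empty + (tabulate(idx, Nc) == 0)
    }
  })
  degenerate <- ids[empty / n_realizations > 0.5]
  if (length(degenerate))
    warning("degenerate territories (empty in >50% of realizations): ",
            paste(degenerate, collapse = ", "))

  mu <- colMeans(F)
  sigma <- if (distance_noise == 0 && mbf_noise == 0)
    matrix(0, Nc, Nc) else stats::cov(F)
  sigma <- psd_repair((sigma + t(sigma)) / 2)
  dimnames(sigma) <- list(ids, ids)

  structure(list(mean = stats::setNames(mu, ids), sigma = sigma,
                 n_realizations = n_realizations, outlet_ids = ids,
                 realizations = if (keep_realizations) F else NULL,
                 distance_noise = distance_noise, mbf_noise = mbf_noise,
                 degenerate = degenerate),
            class = "flow_target_set")
}

#' Clip a symmetric matrix to positive semi-definiteness
#'
#' Eigenvalues below `tol * trace` are raised to that floor (0 for a zero
#' matrix). Used to repair sampling noise in estimated covariances.
#'
#' @param S symmetric matrix.
#' @param tol relative eigenvalue floor.
#' @return Repaired matrix.
#' @export
psd_repair <- function(S, tol = 1e-12) {
  e <- eigen(S, symmetric = TRUE)
  floor_ <- tol * sum(pmax(e$values, 0))
  if (all(e$values >= floor_)) return(S)
  v <- pmax(e$values, floor_)
  e$vectors %*% (v * t(e$vectors))
}

#' Serialize / read a flow-target set (JSON + optional realizations CSV)
#'
#' @param targets a `flow_target_set`.
#' @param path JSON output path; realizations (if kept) go to
#'   `<path>.realizations.csv`.
#' @return `path` (write) or a `flow_target_set` (read).
#' @export
write_flow_targets <- function(targets, path) {
  obj <- list(schema_version = 1L,
              outlet_ids = targets$outlet_ids,
              mean = unname(targets$mean),
              sigma = unname(targets$sigma),
              n_realizations = targets$n_realizations,
              distance_noise = targets$distance_noise,
              mbf_noise = targets$mbf_noise)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(targets$realizations))
    utils::write.csv(as.data.frame(targets$realizations),
                     paste0(path, ".realizations.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_flow_targets
#' @export
read_flow_targets <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ids <- obj$outlet_ids
  sigma <- matrix(unlist(obj$sigma), length(ids), length(ids))
  dimnames(sigma) <- list(ids, ids)
  rpath <- paste0(path, ".realizations.csv")
  structure(list(mean = stats::setNames(obj$mean, ids), sigma = sigma,
                 n_realizations = obj$n_realizations, outlet_ids = ids,
                 realizations = if (file.exists(rpath))
                   as.matrix(utils::read.csv(rpath)) else NULL,
                 distance_noise = obj$distance_noise,
                 mbf_noise = obj$mbf_noise, degenerate = character(0)),
            class = "flow_target_set")
}
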