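# Seeded synthetic fixtures: coronary trees, LV point clouds, MBF fields.
#
# These emulate the statistical structure of the clinical inputs (a coronary
# anatomy with three main epicardial vessels and one stenosis per vessel, an
# LV myocardial point cloud with a smooth perfusion field) at a scale where
# tests run in seconds. They are first-class, deterministic generators: pure
# functions of (configuration, seed).

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random-number state set from `seed` and
#' restores the previous state afterwards, so seeded draws never disturb
#' the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic coronary-tree description
#'
#' Builds a binary branching tree with three main vessels (LAD, LCx via the
#' left main, and RCA), tapering diameters (every child strictly narrower
#' than its parent), one stenosis per main vessel, and outlet coordinates on
#' an epicardial shell around the LV. The first `n_lv` outlets in tree order
#' are flagged as LV-perfusing (LAD and LCx outlets first, then RCA outlets;
#' with the default right-dominant layout the non-LV outlets are RCA
#' marginal branches supplying the RV).
#'
#' @param n_outlets total number of coronary outlets (>= 3).
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param n_lv number of LV-perfusing outlets (<= n_outlets).
#' @param severities named stenosis severities (fractional area reduction)
#'   for the three main vessels.
#' @param root_diameters main-vessel root diameters (cm).
#' @param lv_axes semi-axes of the LV ellipsoid (cm) used to place outlets.
#' @return A tree description data.frame (see [read_coronary_tree()]).
#' @export
generate_tree <- function(n_outlets = 16, seed = 1, n_lv = NULL,
                          severities = c(LAD = 0.60, LCx = 0.50, RCA = 0.55),
                          root_diameters = c(LAD = 0.34, LCx = 0.31, RCA = 0.33),
                          lv_axes = c(3.3, 3.3, 4.4)) {
  stopifnot(n_outlets >= 3)
  n_lv <- n_lv %||% max(3, n_outlets - 2)
  stopifnot(n_lv >= 1, n_lv <= n_outlets)
  with_seed(seed, {
    # outlets per main vessel (LAD largest territory)
    k <- c(LAD = ceiling(0.4 * n_outlets), LCx = 0, RCA = 0)
    k["LCx"] <- max(1, floor(0.3 * n_outlets))
    k["RCA"] <- n_outlets - k["LAD"] - k["LCx"]
    if (k["RCA"] < 1) { k["RCA"] <- 1; k["LAD"] <- n_outlets - 2; k["LCx"] <- 1 }

    rows <- list(); next_id <- 1L
    add_row <- function(parent, len, dia, sev, outlet, lv, xyz) {
      rows[[length(rows) + 1]] <<- data.frame(
        branch_id = next_id, parent_id = parent, length_cm = len,
        diameter_cm = dia, stenosis_severity = sev,
        outlet_flag = as.integer(outlet), perfuses_LV_flag = as.integer(lv),
        outlet_x = xyz[1], outlet_y = xyz[2], outlet_z = xyz[3])
      id <- next_id; next_id <<- next_id + 1L; id
    }

    # angular sectors on the LV shell for each main vessel
    sector <- list(LAD = c(-0.4 * pi, 0.25 * pi),
                   LCx = c(0.25 * pi, 0.9 * pi),
                   RCA = c(0.9 * pi, 1.6 * pi))
    shell_point <- function(phi, frac) {
      # frac in [0,1]: base (0) to apex (1); epicardial shell at 1.05x axes
      th <- (0.15 + 0.7 * frac) * pi
      1.05 * lv_axes * c(sin(th) * cos(phi), sin(th) * sin(phi), cos(th))
    }

    # left main feeding LAD and LCx
    lm_id <- add_row(0L, 1.0, 0.40, 0, FALSE, FALSE, c(0, 0, 0))

    build_main <- function(name, parent0, k_out) {
      d <- root_diameters[[name]]
      sev <- severities[[name]]
      parent <- parent0
      # stenosis on the first trunk segment of each main vessel
      for (i in seq_len(k_out)) {
        frac <- (i - 0.5) / k_out
        phi <- sector[[name]][1] +
          diff(sector[[name]]) * (i - 0.5) / k_out + stats::runif(1, -0.05, 0.05)
        len_trunk <- stats::runif(1, 1.2, 2.2)
        if (i < k_out) {
          trunk <- add_row(parent, len_trunk, d,
                           if (i == 1) sev else 0, FALSE, FALSE, c(0, 0, 0))
          # side-branch outlet
          add_row(trunk, stats::runif(1, 1.0, 2.0), 0.62 * d, 0, TRUE,
                  NA, shell_point(phi, frac))
          d <- d * stats::runif(1, 0.88, 0.94)   # taper, child < parent
          parent <- trunk
        } else {
          # terminal outlet of the trunk
          add_row(parent, stats::runif(1, 1.2, 2.2), 0.9 * d,
                  if (k_out == 1) sev else 0, TRUE, NA,
                  shell_point(phi, frac))
        }
      }
    }

    build_main("LAD", lm_id, k[["LAD"]])
    build_main("LCx", lm_id, k[["LCx"]])
    build_main("RCA", 0L, k[["RCA"]])

    tree <- do.call(rbind, rows)
    # LV perfusion flags: first n_lv outlets in tree order perfuse the LV
    out_rows <- which(tree$outlet_flag == 1)
    tree$perfuses_LV_flag <- 0L
    tree$perfuses_LV_flag[out_rows[seq_len(n_lv)]] <- 1L
    rownames(tree) <- NULL
    tree
  })
}

#' MBF field profile for the synthetic LV
#'
#' @param base baseline myocardial blood flow (mL/min per mL tissue);
#'   the default is a typical hyperemic level.
#' @param smooth_amp amplitude of the smooth base-to-apex / circumferential
#'   modulation (fraction of `base`).
#' @param deficit_center optional length-3 center of a regional perfusion
#'   deficit (cm); NULL for none.
#' @param deficit_scale fractional MBF reduction at the deficit center
#'   (0 = no deficit).
#' @param deficit_radius Gaussian radius of the deficit (cm).
#' @param total_flow optional target total LV flow (mL/min); if given, the
#'   field is rescaled so that sum(mbf * voxel_volume) equals it exactly.
#' @return A list of class `lv_profile`.
#' @export
lv_profile <- function(base = 2.0, smooth_amp = 0.15,
                       deficit_center = NULL, deficit_scale = 0,
                       deficit_radius = 1.5, total_flow = NULL) {
  structure(list(base = base, smooth_amp = smooth_amp,
                 deficit_center = deficit_center,
                 deficit_scale = deficit_scale,
                 deficit_radius = deficit_radius,
                 total_flow = total_flow), class = "lv_profile")
}

#' Generate a synthetic LV point cloud with an MBF field
#'
#' Samples points uniformly in an ellipsoidal myocardial shell (inner scale
#' `wall_inner` of the outer surface), assigns each an equal voxel volume so
#' that the total equals the shell volume, and evaluates a smooth MBF field
#' (optionally with a regional deficit mimicking disease).
#'
#' @param n_points number of points (>= 100).
#' @param seed integer seed.
#' @param mbf_profile an [lv_profile()].
#' @param lv_axes outer semi-axes of the LV ellipsoid (cm).
#' @param wall_inner inner surface as a fraction of the outer axes.
#' @return An object of class `lv_cloud`: list with `points` (n x 3 matrix,
#'   cm), `voxel_volume` (cm3 per point), `mbf` (mL/min per mL).
#' @export
generate_lv <- function(n_points = 5000, seed = 1,
                        mbf_profile = lv_profile(),
                        lv_axes = c(3.3, 3.3, 4.4), wall_inner = 0.7) {
  stopifnot(n_points >= 100)
  with_seed(seed, {
    u <- matrix(stats::rnorm(3 * n_points), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    # uniform in the shell: radius^3 uniform between inner^3 and 1
    r <- (stats::runif(n_points, wall_inner^3, 1))^(1 / 3)
    pts <- u * r
    pts <- sweep(pts, 2, lv_axes, `*`)
    vol_shell <- 4 / 3 * pi * prod(lv_axes) * (1 - wall_inner^3)
    vv <- vol_shell / n_points

    pr <- mbf_profile
    mbf <- rep(pr$base, n_points)
    if (pr$smooth_amp > 0) {
      ph <- atan2(pts[, 2], pts[, 1])
      zn <- pts[, 3] / lv_axes[3]
      mbf <- mbf * (1 + pr$smooth_amp * 0.5 * (sin(ph) + zn))
    }
    if (!is.null(pr$deficit_center) && pr$deficit_scale > 0) {
      d2 <- rowSums(sweep(pts, 2, pr$deficit_center)^2)
      mbf <- mbf * (1 - pr$deficit_scale * exp(-d2 / (2 * pr$deficit_radius^2)))
    }
    if (!is.null(pr$total_flow)) {
      mbf <- mbf * pr$total_flow / sum(mbf * vv)
    }
    structure(list(points = pts, voxel_volume = vv, mbf = mbf,
                   axes = lv_axes), class = "lv_cloud")
  })
}

#' Write / read the LV point-cloud CSV format {x, y, z, voxel_volume, mbf}
#'
#' @param lv an `lv_cloud`.
#' @param path file path.
#' @return `path` (write) or an `lv_cloud` (read).
#' @export
write_lv_csv <- function(lv, path) {
  df <- data.frame(x = lv$points[, 1], y = lv$points[, 2], z = lv$points[, 3],
                   voxel_volume = lv$voxel_volume, mbf = lv$mbf)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lv_csv
#' @export
read_lv_csv <- function(path) {
  df <- utils::read.csv(path)
  structure(list(points = as.matrix(df[, c("x", "y", "z")]),
                 voxel_volume = df$voxel_volume[1], mbf = df$mbf),
            class = "lv_cloud")
}

#' Total LV flow of a point cloud
#'
#' @param lv an `lv_cloud`.
#' @return Sum of mbf * voxel_volume (mL/min).
#' @export
total_lv_flow <- function(lv) sum(lv$mbf * lv$voxel_volume)
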