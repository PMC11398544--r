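# End-to-end pipeline orchestration: synthetic fixtures -> perfusion flow
# targets -> Bayesian personalization -> input sampling -> multi-fidelity
# estimation; every stage serializes machine-readable artifacts and the run
# is reproducible from (config, seed) alone.

#' Pipeline configuration
#'
#' Stage toggles plus the scale parameters of every stage. The defaults are
#' a desk-scale smoke configuration; production-scale values (2500 target
#' realizations, 24 x 10000 MCMC generations, N0D = 10000) are set by
#' raising the corresponding entries.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir output directory.
#' @param stages character subset of
#'   c("fixtures", "targets", "personalize", "estimate").
#' @param n_outlets,n_lv,n_points tree/LV fixture scale.
#' @param n_realizations flow-target noise realizations.
#' @param n_chains,n_generations DREAM sampler size.
#' @param qoi QoI spec for the estimation stage (default: mean flow of the
#'   first stenosed LV branch's outlet).
#' @param n_pilot,n_extra pilot (paired) and additional LF-only sample
#'   counts.
#' @param ae an [ae_config()] for the shared-space stage.
#' @param hyperemia_factor distal coronary resistance scaling.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("corouq_run_"),
                            stages = c("fixtures", "targets", "personalize",
                                       "estimate"),
                            n_outlets = 16, n_lv = 14, n_points = 1500,
                            n_realizations = 300,
                            n_chains = 12, n_generations = 600,
                            qoi = NULL, n_pilot = 80, n_extra = 400,
                            ae = ae_config(epochs = 300, stage2_epochs = 200,
                                           patience = 10),
                            hyperemia_factor = 0.24) {
  structure(list(seed = seed, out_dir = out_dir, stages = stages,
                 n_outlets = n_outlets, n_lv = n_lv, n_points = n_points,
                 n_realizations = n_realizations, n_chains = n_chains,
                 n_generations = n_generations, qoi = qoi,
                 n_pilot = n_pilot, n_extra = n_extra, ae = ae,
                 hyperemia_factor = hyperemia_factor,
                 schema_version = 1L),
            class = "pipeline_config")
}

stage_log <- function(run, stage, ...) {
  msg <- paste0("[", stage, "] ", ...)
  cat(msg, "\n", file = file.path(run, "pipeline.log"), append = TRUE)
}

#' Run the pipeline
#'
#' Executes the enabled stages in order; later stages read the serialized
#' outputs of earlier ones from the run directory, so a run can be resumed
#' or partially re-executed. Writes `summary.json` with a provenance block
#' (seed, config hash, package version) and per-stage artifacts.
#'
#' @param config a [pipeline_config()].
#' @return The run directory path (invisibly); artifacts: `tree.csv`,
#'   `lv.csv`, `targets.json`, `posterior.json` + `chains.csv`,
#'   `estimate_*.json`, `summary.json`, `pipeline.log`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  run <- config$out_dir
  dir.create(run, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(run, "config.json")
  jsonlite::write_json(config[setdiff(names(config), "ae")], cfg_path,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  summary <- list(schema_version = 1L,
                  provenance = list(
                    seed = config$seed,
                    config_md5 = unname(tools::md5sum(cfg_path)),
                    package_version = as.character(
                      utils::packageVersion("coroUQ"))))

  do_stage <- function(name, fn) {
    if (!(name %in% config$stages)) return(NULL)
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fn(), error = function(e)
      stop("pipeline halted in stage '", name, "' (artifacts in ", run,
           "): ", conditionMessage(e), call. = FALSE))
    stage_log(run, name, "done in ", signif(proc.time()[["elapsed"]] - t0, 3),
              " s")
    out
  }

  # ---- fixtures
  do_stage("fixtures", function() {
    tree <- generate_tree(n_outlets = config$n_outlets, seed = config$seed,
                          n_lv = config$n_lv)
    write_coronary_tree(tree, file.path(run, "tree.csv"))
    lv <- generate_lv(n_points = config$n_points, seed = config$seed + 1)
    write_lv_csv(lv, file.path(run, "lv.csv"))
  })

  # ---- targets
  do_stage("targets", function() {
    tree <- read_coronary_tree(file.path(run, "tree.csv"))
    lv <- read_lv_csv(file.path(run, "lv.csv"))
    targets <- build_flow_targets(lv, outlet_set(tree),
                                  n_realizations = config$n_realizations,
                                  seed = config$seed + 2)
    write_flow_targets(targets, file.path(run, "targets.json"))
  })

  # ---- personalize
  posterior <- do_stage("personalize", function() {
    tree <- read_coronary_tree(file.path(run, "tree.csv"))
    targets <- read_flow_targets(file.path(run, "targets.json"))
    net <- apply_hyperemia(build_network(tree), config$hyperemia_factor)
    total_R <- 1 / sum(1 / outlet_resistances_lv(net))
    prior <- prior_spec(reference_resistances(total_R, targets$mean))
    model <- function(r) lv_outlet_flows(net, r)
    ll <- function(r) flow_loglik(r, targets, model)
    post <- dream_sample(ll, prior, n_chains = config$n_chains,
                         n_generations = config$n_generations,
                         seed = config$seed + 3)
    draws <- posterior_draws(post, thin = 10)
    utils::write.csv(as.data.frame(draws), file.path(run, "chains.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(
      schema_version = 1L, seed = post$seed,
      outlet_ids = targets$outlet_ids,
      posterior_mean = unname(colMeans(draws)),
      posterior_sd = unname(apply(draws, 2, stats::sd)),
      gelman_rubin = unname(post$gelman_rubin),
      acceptance_rate = post$acceptance_rate,
      total_resistance = total_R),
      file.path(run, "posterior.json"), auto_unbox = TRUE, digits = NA)
    post
  })

  # ---- estimate
  do_stage("estimate", function() {
    tree <- read_coronary_tree(file.path(run, "tree.csv"))
    net <- apply_hyperemia(build_network(tree), config$hyperemia_factor)
    draws <- as.matrix(utils::read.csv(file.path(run, "chains.csv")))
    qoi_spec <- config$qoi %||% {
      sten <- net$segments[net$segments$S > 0 & net$segments$perfuses_LV, ]
      if (nrow(sten) == 0) {
        sten_seg <- net$segments$id[which(net$segments$S > 0)[1]]
        kids_out <- net$coronary_bc$outlet_id[1]
      }
      # outlet downstream of the first stenosed segment
      first_sten <- which(net$segments$S > 0)[1]
      desc <- first_sten
      repeat {
        kids <- which(net$parent %in% desc)
        if (!length(setdiff(kids, desc))) break
        desc <- union(desc, kids)
      }
      out_seg <- intersect(desc, net$coronary_bc$seg)[1]
      paste0("mean_flow:", net$segments$id[out_seg])
    }
    theta <- sample_inputs(draws, config$n_pilot + config$n_extra,
                           seed = config$seed + 4)
    lf_fun <- function(X) {
      X <- as.matrix(X)
      d <- ncol(X) - 1
      vapply(seq_len(nrow(X)), function(i) {
        neti <- apply_inputs_to_network(net, pmax(X[i, seq_len(d)], 1e-3),
                                        min(max(X[i, d + 1], 0.1), 10))
        qoi_from_0d(steady_flow_split(neti), qoi_spec)
      }, 0)
    }
    hf_cfg <- hf_surrogate_config(net, qoi_spec, inner = "steady",
                                  distortion = "osi_proxy",
                                  calibrate_inputs = theta)
    pilot <- theta[seq_len(config$n_pilot), , drop = FALSE]
    extra <- theta[-seq_len(config$n_pilot), , drop = FALSE]
    hf_vals <- hf_surrogate(pilot, hf_cfg)
    lf_pilot <- lf_fun(pilot)
    lf_extra <- lf_fun(extra)

    est_mc <- mc_estimate(hf_vals)
    est_mfmc <- mfmc_estimate(sample_pair_set(hf_vals, lf_pilot, lf_extra))
    m3 <- train_stage1(pilot, hf_vals, config$ae, seed = config$seed + 5)
    m0 <- train_stage1(pilot, lf_pilot, config$ae, seed = config$seed + 6)
    map <- train_stage2(m3, m0, pilot, hf_vals, pilot, lf_pilot,
                        config$ae, seed = config$seed + 7,
                        lf_at_hf = lf_pilot, lf_fun = lf_fun)
    est_ae <- mfmc_ae_estimate(map, pilot, hf_vals, extra)

    write_estimator_report(est_mc, file.path(run, "estimate_mc.json"))
    write_estimator_report(est_mfmc, file.path(run, "estimate_mfmc.json"))
    write_estimator_report(est_ae, file.path(run, "estimate_mfmc_ae.json"))
    jsonlite::write_json(list(schema_version = 1L, qoi = qoi_spec,
                              rho = map$rho, rho_ae = map$rho_ae),
                         file.path(run, "correlations.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  # ---- summary
  for (f in c("targets.json", "posterior.json", "correlations.json",
              "estimate_mc.json", "estimate_mfmc.json",
              "estimate_mfmc_ae.json")) {
    p <- file.path(run, f)
    if (file.exists(p))
      summary[[sub("\\.json$", "", f)]] <-
        jsonlite::read_json(p, simplifyVector = TRUE)
  }
  jsonlite::write_json(summary, file.path(run, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(run)
}

#' Human-readable report of a pipeline run
#'
#' @param run_dir a directory written by [run_pipeline()].
#' @return A list of data.frames (posterior summary, estimator table),
#'   invisibly; prints a formatted report. Missing artifacts are listed and
#'   a partial report is produced.
#' @export
report <- function(run_dir) {
  p <- file.path(run_dir, "summary.json")
  if (!file.exists(p)) stop("no summary.json in ", run_dir)
  s <- jsonlite::read_json(p, simplifyVector = TRUE)
  out <- list()
  missing <- character(0)
  cat("== coroUQ pipeline report ==\n")
  cat("seed:", s$provenance$seed, " config:", s$provenance$config_md5, "\n")
  if (!is.null(s$posterior)) {
    out$posterior <- data.frame(outlet = s$posterior$outlet_ids,
                                mean = s$posterior$posterior_mean,
                                sd = s$posterior$posterior_sd,
                                gelman_rubin = s$posterior$gelman_rubin)
    cat("\nPosterior outlet resistances (max R-hat ",
        signif(max(out$posterior$gelman_rubin), 4), "):\n", sep = "")
    print(out$posterior, digits = 4)
  } else missing <- c(missing, "posterior")
  est <- list()
  for (k in c("estimate_mc", "estimate_mfmc", "estimate_mfmc_ae")) {
    if (!is.null(s[[k]])) est[[k]] <- s[[k]] else missing <- c(missing, k)
  }
  if (length(est)) {
    out$estimators <- do.call(rbind, lapply(est, function(e)
      data.frame(estimator = e$estimator, mean = e$mean,
                 sd = sqrt(e$variance), rho = e$rho,
                 ci95_half = (e$ci95[2] - e$ci95[1]) / 2,
                 ci99_half = (e$ci99[2] - e$ci99[1]) / 2,
                 N3D = e$N3D, N0D = e$N0D)))
    rownames(out$estimators) <- NULL
    cat("\nEstimators (one row per estimator):\n")
    print(out$estimators, digits = 4)
    hw <- out$estimators$ci95_half
    cat("\n95% interval half-width ratios (MC : MFMC : MFMC-AE): ",
        paste(signif(hw / hw[1], 3), collapse = " : "), "\n", sep = "")
  }
  if (!is.null(s$correlations))
    cat("\nCorrelation: rho = ", signif(s$correlations$rho, 4),
        " -> rho_AE = ", signif(s$correlations$rho_ae, 4), "\n", sep = "")
  if (length(missing))
    cat("\nMissing artifacts:", paste(missing, collapse = ", "), "\n")
  invisible(out)
}
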