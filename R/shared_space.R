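# Shared-space construction between low- and high-fidelity models.
#
# Each fidelity gets a supervised autoencoder (encoder E: R^d -> R, decoder
# D: R -> R^d, surrogate head Q_NN: R -> R) trained so the 1D latent
# captures the full variation of the QoI. The two latent distributions are
# linked through analytic 1D normalizing flows (empirical CDF to U(0,1) to
# N(0,1)), yielding a common standard-Gaussian shared space. The
# low-fidelity model is then *resampled* at the locations that correspond,
# within the shared space, to the high-fidelity inputs:
#   Q_AE(theta_hf) = Q_lf( D_lf( T_lf^-1( T_hf( E_hf(theta_hf) ) ) ) ),
# which raises the low/high-fidelity output correlation and thereby the
# variance reduction of the multi-fidelity estimator.

#' Autoencoder / shared-space training configuration
#'
#' Small-network defaults chosen for the low-sample regime (pilot sizes down
#' to 25): 2 hidden layers x 32 units, tanh activations, full-batch Adam.
#'
#' @param hidden hidden-layer widths of encoder/decoder/surrogate head.
#' @param latent_dim latent dimension; only 1 is supported (the analytic
#'   flow construction is specific to 1D).
#' @param lr Adam learning rate.
#' @param weight_decay decoupled L2 weight decay (combats small-sample
#'   overfitting).
#' @param epochs stage-1 epoch cap.
#' @param val_frac validation fraction for early stopping.
#' @param val_every validation check interval (epochs).
#' @param patience early-stopping patience (validation checks).
#' @param stage2_epochs stage-2 epoch cap.
#' @param corr_weight weight of the correlation bonus in the stage-2 loss.
#' @param flow_refit_every refit interval (epochs) of the empirical-CDF
#'   flows during stage 2 (the latent distribution moves as weights train).
#' @param flow_eps CDF clipping bound of the flows.
#' @return List of class `ae_config`.
#' @export
ae_config <- function(hidden = c(32, 32), latent_dim = 1, lr = 3e-3,
                      weight_decay = 1e-4,
                      epochs = 3000, val_frac = 0.2, val_every = 10,
                      patience = 30, stage2_epochs = 1500, corr_weight = 1,
                      flow_refit_every = 10, flow_eps = 1e-4) {
  if (latent_dim != 1)
    stop("latent_dim > 1 is not supported: the shared space uses analytic ",
         "1D flows")
  structure(list(hidden = hidden, latent_dim = latent_dim, lr = lr,
                 weight_decay = weight_decay,
                 epochs = epochs, val_frac = val_frac, val_every = val_every,
                 patience = patience, stage2_epochs = stage2_epochs,
                 corr_weight = corr_weight,
                 flow_refit_every = flow_refit_every, flow_eps = flow_eps),
            class = "ae_config")
}

lr_at <- function(config, ep, total) {
  # cosine decay from lr to lr/10 over the epoch budget
  lo <- config$lr / 10
  lo + 0.5 * (config$lr - lo) * (1 + cos(pi * min(ep / total, 1)))
}

std_apply <- function(X, center, scale) sweep(sweep(X, 2, center), 2, scale, `/`)
std_undo <- function(X, center, scale) sweep(sweep(X, 2, scale, `*`), 2, center, `+`)

grads_of <- function(b) list(dW = b$dW, db = b$db)

# forward + backward of the four-term supervised-autoencoder loss:
#   MSE(y, Q(E x)) + MSE(y, Q(E D E x)) + MSE(Q(E x), Q(E D E x))
#   + MSE(D E x, D E D E x)
stage1_pass <- function(enc, dec, head, X, y, backward = TRUE) {
  n <- nrow(X)
  fe <- mlp_forward(enc, X);   e <- fe$out
  fd <- mlp_forward(dec, e);   xr <- fd$out
  fe2 <- mlp_forward(enc, xr); er <- fe2$out
  fq1 <- mlp_forward(head, e);  q1 <- fq1$out
  fq2 <- mlp_forward(head, er); q2 <- fq2$out
  fd2 <- mlp_forward(dec, er); xrr <- fd2$out
  loss <- mean((y - q1)^2) + mean((y - q2)^2) + mean((q1 - q2)^2) +
    mean((xr - xrr)^2)
  out <- list(loss = loss, e = e, xr = xr, xrr = xrr, q1 = q1)
  if (!backward) return(out)

  dq1 <- 2 * ((q1 - y) + (q1 - q2)) / n
  dq2 <- 2 * ((q2 - y) - (q1 - q2)) / n
  dxr <- 2 * (xr - xrr) / length(xr)
  dxrr <- -dxr
  gd2 <- mlp_backward(dec, fd2, dxrr)
  gq2 <- mlp_backward(head, fq2, dq2)
  ge2 <- mlp_backward(enc, fe2, gd2$dX + gq2$dX)
  gd1 <- mlp_backward(dec, fd, dxr + ge2$dX)
  gq1 <- mlp_backward(head, fq1, dq1)
  ge1 <- mlp_backward(enc, fe, gd1$dX + gq1$dX)
  out$genc <- grads_add(grads_of(ge1), grads_of(ge2))
  out$gdec <- grads_add(grads_of(gd1), grads_of(gd2))
  out$ghead <- grads_add(grads_of(gq1), grads_of(gq2))
  out
}

#' Stage-1 training of a supervised autoencoder
#'
#' Minimizes the four-term loss combining surrogate accuracy (QoI vs the
#' latent surrogate head), reconstruction-consistency of the surrogate, and
#' reconstruction idempotence, so the 1D latent coordinate captures the
#' QoI's active manifold.
#'
#' @param inputs matrix (n x d) of model inputs (raw scale; z-scored
#'   internally with stored statistics).
#' @param qoi_values length-n QoI values.
#' @param config an [ae_config()].
#' @param seed integer seed (weight init and validation split).
#' @return Object of class `ae_model`: encoder/decoder/head networks,
#'   standardization statistics, training history.
#' @export
train_stage1 <- function(inputs, qoi_values, config = ae_config(), seed = 1) {
  X <- as.matrix(inputs); y <- as.numeric(qoi_values)
  n <- nrow(X); d <- ncol(X)
  if (n < 25) stop("need at least 25 training samples")
  xc <- colMeans(X); xs <- pmax(apply(X, 2, stats::sd), 1e-12)
  yc <- mean(y); ys <- max(stats::sd(y), 1e-12)
  Xs <- std_apply(X, xc, xs); ysv <- matrix((y - yc) / ys, ncol = 1)

  with_seed(seed, {
    enc <- mlp_init(c(d, config$hidden, 1))
    dec <- mlp_init(c(1, config$hidden, d))
    head <- mlp_init(c(1, config$hidden, 1))
    iv <- sample.int(n, max(2, round(config$val_frac * n)))
    Xtr <- Xs[-iv, , drop = FALSE]; ytr <- ysv[-iv, , drop = FALSE]
    Xva <- Xs[iv, , drop = FALSE]; yva <- ysv[iv, , drop = FALSE]

    se <- adam_init(enc); sd_ <- adam_init(dec); sh <- adam_init(head)
    best <- list(val = Inf, enc = enc, dec = dec, head = head)
    bad <- 0; hist_tr <- numeric(0); hist_va <- numeric(0)
    for (ep in seq_len(config$epochs)) {
      ps <- stage1_pass(enc, dec, head, Xtr, ytr)
      if (!is.finite(ps$loss)) stop("non-finite stage-1 loss at epoch ", ep)
      lr <- lr_at(config, ep, config$epochs)
      up <- adam_step(enc, ps$genc, se, lr, config$weight_decay); enc <- up$net; se <- up$state
      up <- adam_step(dec, ps$gdec, sd_, lr, config$weight_decay); dec <- up$net; sd_ <- up$state
      up <- adam_step(head, ps$ghead, sh, lr, config$weight_decay); head <- up$net; sh <- up$state
      if (ep %% config$val_every == 0) {
        va <- stage1_pass(enc, dec, head, Xva, yva, backward = FALSE)$loss
        hist_tr <- c(hist_tr, ps$loss); hist_va <- c(hist_va, va)
        if (va < best$val - 1e-12) {
          best <- list(val = va, enc = enc, dec = dec, head = head); bad <- 0
        } else {
          bad <- bad + 1
          if (bad >= config$patience) break
        }
      }
    }
    structure(list(enc = best$enc, dec = best$dec, head = best$head,
                   x_center = xc, x_scale = xs, y_center = yc, y_scale = ys,
                   d = d, config = config, seed = seed,
                   history = list(train = hist_tr, val = hist_va)),
              class = "ae_model")
  })
}

#' Encode inputs to the 1D latent coordinate
#'
#' @param model an `ae_model`.
#' @param inputs matrix (n x d), raw scale.
#' @return Numeric vector of latent values.
#' @export
ae_encode <- function(model, inputs) {
  drop(mlp_forward(model$enc,
                   std_apply(as.matrix(inputs), model$x_center,
                             model$x_scale))$out)
}

#' Decode latent coordinates to input space
#'
#' @param model an `ae_model`.
#' @param z latent values.
#' @return Matrix (n x d) on the raw input scale.
#' @export
ae_decode <- function(model, z) {
  xr <- mlp_forward(model$dec, matrix(z, ncol = 1))$out
  std_undo(xr, model$x_center, model$x_scale)
}

#' Surrogate-head QoI prediction
#'
#' @param model an `ae_model`.
#' @param inputs matrix (n x d), raw scale.
#' @return Predicted QoI values (raw scale).
#' @export
ae_predict <- function(model, inputs) {
  z <- ae_encode(model, inputs)
  drop(mlp_forward(model$head, matrix(z, ncol = 1))$out) * model$y_scale +
    model$y_center
}

#' Stage-2 joint training into a shared space
#'
#' Fine-tunes both autoencoders (initialized from stage 1) under
#' L_hf + L_lf - corr_weight * |rho(Q_hf, Q_NN_lf(T_lf^-1 T_hf E_hf(x_hf)))|,
#' the correlation bonus being evaluated through the latent surrogate head
#' of the low-fidelity model (the printed form; resampling the true
#' low-fidelity model afterwards uses [resample_lf()]). The empirical-CDF
#' flows are held fixed between refits and refit every `flow_refit_every`
#' epochs from the current latent samples.
#'
#' @param hf_model,lf_model stage-1 `ae_model`s.
#' @param hf_inputs,hf_values high-fidelity pilot inputs and QoI values.
#' @param lf_inputs,lf_values low-fidelity training inputs and QoI values.
#' @param config an [ae_config()].
#' @param seed integer seed.
#' @param lf_at_hf optional low-fidelity values at the HF pilot inputs, used
#'   to record the original correlation rho.
#' @param lf_fun optional vectorized low-fidelity model function(inputs
#'   matrix) -> values; stored for [resample_lf()] and used to record
#'   rho_AE.
#' @return Object of class `shared_space_map`.
#' @export
train_stage2 <- function(hf_model, lf_model, hf_inputs, hf_values,
                         lf_inputs, lf_values, config = ae_config(),
                         seed = 1, lf_at_hf = NULL, lf_fun = NULL) {
  X3 <- std_apply(as.matrix(hf_inputs), hf_model$x_center, hf_model$x_scale)
  y3 <- matrix((hf_values - hf_model$y_center) / hf_model$y_scale, ncol = 1)
  X0 <- std_apply(as.matrix(lf_inputs), lf_model$x_center, lf_model$x_scale)
  y0 <- matrix((lf_values - lf_model$y_center) / lf_model$y_scale, ncol = 1)
  yv <- drop(y3)
  if (stats::sd(yv) == 0) stop("zero-variance high-fidelity QoI")

  enc3 <- hf_model$enc; dec3 <- hf_model$dec; head3 <- hf_model$head
  enc0 <- lf_model$enc; dec0 <- lf_model$dec; head0 <- lf_model$head

  with_seed(seed, {
    s3e <- adam_init(enc3); s3d <- adam_init(dec3); s3h <- adam_init(head3)
    s0e <- adam_init(enc0); s0d <- adam_init(dec0); s0h <- adam_init(head0)
    refit <- function() {
      list(hf = fit_flow(drop(mlp_forward(enc3, X3)$out), config$flow_eps),
           lf = fit_flow(drop(mlp_forward(enc0, X0)$out), config$flow_eps))
    }
    fl <- refit()
    # checkpoint quality: when the (cheap) low-fidelity model is available,
    # select the checkpoint maximizing the true resampled correlation;
    # otherwise fall back to the training loss
    rho_true_now <- function() {
      z3 <- drop(mlp_forward(enc3, X3)$out)
      tr <- flow_transfer(fl$hf, fl$lf, z3)
      th0 <- std_undo(mlp_forward(dec0, matrix(tr$z, ncol = 1))$out,
                      lf_model$x_center, lf_model$x_scale)
      stats::cor(hf_values, lf_fun(th0))
    }
    use_true <- !is.null(lf_fun)
    best <- list(loss = Inf, rho_true = -Inf)
    bad <- 0; rho_trace <- numeric(0)
    for (ep in seq_len(config$stage2_epochs)) {
      p3 <- stage1_pass(enc3, dec3, head3, X3, y3)
      p0 <- stage1_pass(enc0, dec0, head0, X0, y0)

      # correlation bonus through the shared space
      fe3 <- mlp_forward(enc3, X3)
      tr <- flow_transfer(fl$hf, fl$lf, drop(fe3$out))
      fz0 <- matrix(tr$z, ncol = 1)
      fq0 <- mlp_forward(head0, fz0)
      v <- drop(fq0$out)
      vc <- v - mean(v); ac <- yv - mean(yv)
      nv <- sqrt(sum(vc^2)); na <- sqrt(sum(ac^2))
      if (nv < 1e-12)
        stop("correlation term undefined: zero variance of the resampled ",
             "surrogate output")
      rho <- sum(ac * vc) / (na * nv)
      dv <- -config$corr_weight * sign(rho) *
        (ac / (na * nv) - rho * vc / nv^2)
      gq0c <- mlp_backward(head0, fq0, matrix(dv, ncol = 1))
      dz3 <- gq0c$dX * tr$slope
      ge3c <- mlp_backward(enc3, fe3, dz3)

      loss <- p3$loss + p0$loss - config$corr_weight * abs(rho)
      if (!is.finite(loss)) stop("non-finite stage-2 loss at epoch ", ep)
      rho_trace <- c(rho_trace, rho)

      genc3 <- grads_add(p3$genc, grads_of(ge3c))
      ghead0 <- grads_add(p0$ghead, grads_of(gq0c))
      lr <- lr_at(config, ep, config$stage2_epochs)
      up <- adam_step(enc3, genc3, s3e, lr, config$weight_decay); enc3 <- up$net; s3e <- up$state
      up <- adam_step(dec3, p3$gdec, s3d, lr, config$weight_decay); dec3 <- up$net; s3d <- up$state
      up <- adam_step(head3, p3$ghead, s3h, lr, config$weight_decay); head3 <- up$net; s3h <- up$state
      up <- adam_step(enc0, p0$genc, s0e, lr, config$weight_decay); enc0 <- up$net; s0e <- up$state
      up <- adam_step(dec0, p0$gdec, s0d, lr, config$weight_decay); dec0 <- up$net; s0d <- up$state
      up <- adam_step(head0, ghead0, s0h, lr, config$weight_decay); head0 <- up$net; s0h <- up$state

      if (ep %% config$flow_refit_every == 0) {
        fl <- refit()
        rt <- if (use_true) abs(rho_true_now()) else NA_real_
        better <- if (use_true) is.finite(rt) && rt > best$rho_true + 1e-12
          else loss < best$loss - 1e-12
        if (better) {
          best <- list(loss = loss, rho_true = rt,
                       enc3 = enc3, dec3 = dec3, head3 = head3,
                       enc0 = enc0, dec0 = dec0, head0 = head0, fl = fl)
          bad <- 0
        } else {
          bad <- bad + 1
          if (bad >= config$patience) break
        }
      }
    }
    if (!is.null(best$enc3)) {
      enc3 <- best$enc3; dec3 <- best$dec3; head3 <- best$head3
      enc0 <- best$enc0; dec0 <- best$dec0; head0 <- best$head0
      fl <- best$fl
    }

    hf_model$enc <- enc3; hf_model$dec <- dec3; hf_model$head <- head3
    lf_model$enc <- enc0; lf_model$dec <- dec0; lf_model$head <- head0
    map <- structure(list(hf = hf_model, lf = lf_model,
                          flow_hf = fl$hf, flow_lf = fl$lf,
                          config = config, seed = seed, lf_fun = lf_fun,
                          rho_trace = rho_trace, flip = FALSE,
                          rho = if (!is.null(lf_at_hf))
                            stats::cor(hf_values, lf_at_hf) else NA_real_,
                          rho_ae = NA_real_),
                     class = "shared_space_map")
    # canonicalize the (arbitrary) latent orientation: reflect the shared
    # Gaussian space if the resampled correlation comes out negative
    if (!is.null(lf_fun)) {
      map$rho_ae <- stats::cor(hf_values, resample_lf(map, hf_inputs))
      if (is.finite(map$rho_ae) && map$rho_ae < 0) {
        map$flip <- TRUE
        map$rho_ae <- stats::cor(hf_values, resample_lf(map, hf_inputs))
      }
    } else if (length(rho_trace) && utils::tail(rho_trace, 1) < 0) {
      map$flip <- TRUE
    }
    map
  })
}

#' @export
print.shared_space_map <- function(x, ...) {
  cat("<shared_space_map> rho ", signif(x$rho, 4), " -> rho_AE ",
      signif(x$rho_ae, 4), "\n", sep = "")
  invisible(x)
}

#' Resample the low-fidelity model at shared-space locations
#'
#' Applies E_hf -> T_hf -> T_lf^-1 -> D_lf -> Q_lf pointwise: every
#' high-fidelity input is encoded, carried through the shared Gaussian
#' space, decoded into a low-fidelity input, and evaluated with the true
#' low-fidelity model. Deterministic for a fixed trained map; flow-domain
#' clipping events are counted in the `"n_clipped"` attribute (not fatal).
#'
#' @param map a `shared_space_map`.
#' @param hf_inputs matrix of high-fidelity inputs (raw scale).
#' @param lf_fun low-fidelity model function (default: the one stored in
#'   the map).
#' @return Vector of resampled low-fidelity QoI values, index-aligned with
#'   `hf_inputs`.
#' @export
resample_lf <- function(map, hf_inputs, lf_fun = NULL) {
  lf_fun <- lf_fun %||% map$lf_fun
  if (is.null(lf_fun)) stop("no low-fidelity model function available")
  X <- as.matrix(hf_inputs)
  z3 <- ae_encode(map$hf, X)
  tr <- flow_transfer(map$flow_hf, map$flow_lf, z3, flip = isTRUE(map$flip))
  theta0 <- ae_decode(map$lf, tr$z)
  out <- lf_fun(theta0)
  attr(out, "n_clipped") <- sum(tr$clipped)
  out
}

#' Multi-fidelity estimate with the shared-space-resampled low-fidelity
#' model
#'
#' The MFMC estimator with Q_AE in place of the original low-fidelity
#' model: alpha from the pilot pairs, analytic variance with rho_AE.
#'
#' @param map a trained `shared_space_map` (with a stored or supplied
#'   low-fidelity function).
#' @param hf_inputs_pilot pilot inputs (N3D rows) with HF evaluations.
#' @param hf_values HF QoI values at the pilot inputs.
#' @param extra_hf_inputs additional input draws (Delta0D rows) from the
#'   same distribution, evaluated only through the resampled LF model.
#' @param lf_fun optional low-fidelity model override.
#' @param alpha optional fixed control coefficient.
#' @return An `estimator_result` labelled "MFMC-AE".
#' @export
mfmc_ae_estimate <- function(map, hf_inputs_pilot, hf_values,
                             extra_hf_inputs, lf_fun = NULL, alpha = NULL) {
  lf_pilot <- resample_lf(map, hf_inputs_pilot, lf_fun)
  lf_extra <- if (NROW(extra_hf_inputs) > 0)
    resample_lf(map, extra_hf_inputs, lf_fun) else numeric(0)
  pairs <- sample_pair_set(hf_values, as.numeric(lf_pilot),
                           as.numeric(lf_extra))
  mfmc_estimate(pairs, alpha = alpha, label = "MFMC-AE")
}

#' Train a full shared-space map for a model pair
#'
#' Convenience wrapper: draws a pilot sample from the pair's input
#' distribution, evaluates both fidelities, runs stage-1 training for each
#' and stage-2 joint training.
#'
#' @param pair a model pair (see [fixture_pair()]): list with `hf_fun`,
#'   `lf_fun`, `sample_inputs(n)`.
#' @param n_pilot pilot-sample size (paired HF/LF evaluations).
#' @param n_lf additional cheap LF-only evaluations used to train the
#'   low-fidelity autoencoder (mirrors the abundance of low-fidelity
#'   simulations; set to 0 to train the LF side on the pilot only).
#' @param config an [ae_config()].
#' @param seed integer seed.
#' @return A `shared_space_map` with `pilot_inputs`, `pilot_hf`, `pilot_lf`
#'   attached.
#' @export
train_shared_space <- function(pair, n_pilot = 300, n_lf = 1000,
                               config = ae_config(), seed = 1) {
  X <- with_seed(seed, pair$sample_inputs(n_pilot))
  qh <- pair$hf_fun(X)
  ql <- pair$lf_fun(X)
  X0 <- if (n_lf > 0)
    rbind(X, with_seed(seed + 10, pair$sample_inputs(n_lf))) else X
  ql0 <- if (n_lf > 0) c(ql, pair$lf_fun(X0[-seq_len(n_pilot), , drop = FALSE]))
    else ql
  m3 <- train_stage1(X, qh, config, seed = seed + 1)
  m0 <- train_stage1(X0, ql0, config, seed = seed + 2)
  map <- train_stage2(m3, m0, X, qh, X0, ql0, config, seed = seed + 3,
                      lf_at_hf = ql, lf_fun = pair$lf_fun)
  map$pilot_inputs <- X; map$pilot_hf <- qh; map$pilot_lf <- ql
  map
}

#' Pilot-size convergence study of the shared-space framework
#'
#' For each pilot size, repeats independent trials of pilot sampling,
#' two-stage training and correlation measurement; reports the spread of
#' rho, rho_AE and of the plain Monte Carlo mean across trials.
#'
#' @param pair a model pair (see [fixture_pair()]).
#' @param pilot_sizes vector of pilot sizes (each >= 25).
#' @param n_trials trials per size.
#' @param seed integer seed; the full report is reproducible.
#' @param config an [ae_config()] (reduced epochs recommended).
#' @return List with `trials` (data.frame: pilot_size, trial, rho, rho_ae,
#'   mc_mean) and `summary` (per-size means and standard deviations).
#' @export
convergence_study <- function(pair, pilot_sizes = c(25, 50, 100, 200),
                              n_trials = 10, seed = 1, config = ae_config()) {
  stopifnot(all(pilot_sizes >= 25))
  rows <- list()
  for (ns in pilot_sizes) {
    for (tr in seq_len(n_trials)) {
      sd_ <- seed + 1000 * match(ns, pilot_sizes) + tr
      map <- train_shared_space(pair, n_pilot = ns, config = config,
                                seed = sd_)
      rows[[length(rows) + 1]] <- data.frame(
        pilot_size = ns, trial = tr, rho = map$rho, rho_ae = map$rho_ae,
        mc_mean = mean(map$pilot_hf))
    }
  }
  trials <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(trials, trials$pilot_size),
    function(df) data.frame(pilot_size = df$pilot_size[1],
                            rho_mean = mean(df$rho),
                            rho_ae_mean = mean(df$rho_ae),
                            rho_ae_sd = stats::sd(df$rho_ae),
                            mc_mean_sd = stats::sd(df$mc_mean))))
  rownames(summary) <- NULL
  list(trials = trials, summary = summary)
}
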