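# Minimal dense neural networks with manual backpropagation and Adam.
#
# The shared-space machinery needs gradients of composite losses (encoder /
# decoder / surrogate-head compositions, plus a correlation term routed
# through piecewise-linear flow transforms). No autodiff framework is
# available in the target environment, and the networks are tiny (2 hidden
# layers x 32 units on <= 1e3 samples), so forward/backward passes are
# written out explicitly with full-batch training.

mlp_init <- function(sizes, act = "tanh") {
  # sizes: c(d_in, hidden..., d_out); Xavier/Glorot init (caller seeds RNG)
  L <- length(sizes) - 1
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    s <- sqrt(6 / (sizes[l] + sizes[l + 1]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -s, s),
                     sizes[l + 1], sizes[l])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b, act = act, sizes = sizes)
}

mlp_forward <- function(net, X) {
  # X: n x d_in; hidden activations tanh, linear output layer
  L <- length(net$W)
  A <- vector("list", L + 1)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z <- tcrossprod(A[[l]], net$W[[l]])
    Z <- sweep(Z, 2, net$b[[l]], `+`)
    A[[l + 1]] <- if (l < L) tanh(Z) else Z
  }
  list(out = A[[L + 1]], A = A)
}

mlp_backward <- function(net, cache, dOut) {
  # dOut: n x d_out gradient wrt output; returns parameter grads and dX
  L <- length(net$W)
  A <- cache$A
  dW <- vector("list", L); db <- vector("list", L)
  dZ <- dOut
  for (l in L:1) {
    dW[[l]] <- crossprod(dZ, A[[l]])
    db[[l]] <- colSums(dZ)
    dA <- dZ %*% net$W[[l]]
    if (l > 1) dZ <- dA * (1 - A[[l]]^2)   # tanh'
  }
  list(dW = dW, db = db, dX = dA)
}

grads_zero <- function(net) {
  list(dW = lapply(net$W, function(w) array(0, dim(w))),
       db = lapply(net$b, function(b) numeric(length(b))))
}

grads_add <- function(g1, g2) {
  list(dW = Map(`+`, g1$dW, g2$dW), db = Map(`+`, g1$db, g2$db))
}

adam_init <- function(net) {
  list(mW = lapply(net$W, function(w) array(0, dim(w))),
       vW = lapply(net$W, function(w) array(0, dim(w))),
       mb = lapply(net$b, function(b) numeric(length(b))),
       vb = lapply(net$b, function(b) numeric(length(b))),
       t = 0)
}

adam_step <- function(net, grads, state, lr = 1e-3, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$dW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$dW[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps) -
      lr * weight_decay * net$W[[l]]   # decoupled (AdamW-style) decay
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$db[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$db[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(net = net, state = state)
}

#' One-dimensional normalizing flow from the empirical distribution
#'
#' Maps an arbitrarily distributed 1D latent variable to the standard normal
#' by inverse transform sampling: the empirical CDF (piecewise-linear
#' interpolation of the plotting positions (i - 0.5)/n, with edge-slope
#' extrapolation and clipping to [eps, 1 - eps]) composed with the standard
#' normal quantile function. Strictly monotone on its support; the inverse
#' reproduces training samples to interpolation accuracy.
#'
#' @param latent_samples finite numeric vector (>= 20 values, not all
#'   equal).
#' @param eps CDF clipping bound.
#' @return Object of class `flow1d` with fields `knots`, `p`, `eps`.
#' @export
fit_flow <- function(latent_samples, eps = 1e-4) {
  z <- as.numeric(latent_samples)
  stopifnot(all(is.finite(z)))
  if (length(z) < 20) stop("need at least 20 latent samples")
  if (max(z) - min(z) < 1e-12 * max(abs(z), 1))
    stop("constant latent samples: degenerate manifold")
  n <- length(z)
  o <- order(z)
  k <- z[o]; p <- ((1:n) - 0.5) / n
  # collapse duplicate knots (average their positions) to keep monotonicity
  if (anyDuplicated(k)) {
    agg <- tapply(p, k, mean)
    k <- as.numeric(names(agg)); p <- as.numeric(agg)
  }
  structure(list(knots = k, p = p, eps = eps), class = "flow1d")
}

flow_cdf <- function(flow, z) {
  k <- flow$knots; p <- flow$p; n <- length(k)
  i <- pmin(pmax(findInterval(z, k), 1L), n - 1L)
  slope <- (p[i + 1] - p[i]) / (k[i + 1] - k[i])
  u <- p[i] + slope * (z - k[i])
  clipped <- u < flow$eps | u > 1 - flow$eps
  list(u = pmin(pmax(u, flow$eps), 1 - flow$eps), slope = slope,
       clipped = clipped)
}

flow_quantile <- function(flow, u) {
  k <- flow$knots; p <- flow$p; n <- length(k)
  i <- pmin(pmax(findInterval(u, p), 1L), n - 1L)
  slope <- (k[i + 1] - k[i]) / (p[i + 1] - p[i])
  list(z = k[i] + slope * (u - p[i]), slope = slope)
}

#' Forward flow transform: latent value to standard-normal value
#'
#' @param flow a [fit_flow()] object.
#' @param z latent values.
#' @return Standard-normal values T(z).
#' @export
flow_forward <- function(flow, z) stats::qnorm(flow_cdf(flow, z)$u)

#' Inverse flow transform: standard-normal value to latent value
#'
#' @param flow a [fit_flow()] object.
#' @param g standard-normal values.
#' @return Latent values T^-1(g).
#' @export
flow_inverse <- function(flow, g) {
  u <- pmin(pmax(stats::pnorm(g), flow$eps), 1 - flow$eps)
  flow_quantile(flow, u)$z
}

# composite latent transfer z_hf -> z_lf with elementwise slope
# (the qnorm/pnorm Jacobians cancel: dz0/dz3 = cdf-slope_hf * quantile-slope_lf).
# `flip` reflects the shared Gaussian space (g -> -g), which leaves its
# distribution invariant; it canonicalizes the otherwise arbitrary latent
# orientation.
flow_transfer <- function(flow_hf, flow_lf, z, flip = FALSE) {
  fw <- flow_cdf(flow_hf, z)
  g <- stats::qnorm(fw$u)
  if (flip) g <- -g
  u0 <- pmin(pmax(stats::pnorm(g), flow_lf$eps), 1 - flow_lf$eps)
  qv <- flow_quantile(flow_lf, u0)
  list(z = qv$z, slope = (if (flip) -1 else 1) * fw$slope * qv$slope, g = g,
       clipped = fw$clipped)
}
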