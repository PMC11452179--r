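## The digital-twin encoding model: a two-layer space-time-separable CNN core
## shared across neurons plus a per-neuron Gaussian readout, with a
## linearised (LN) variant. Forward and backward passes are written out
## explicitly (matrix algebra + the compiled gather/conv kernels in src/),
## which is what makes gradient-based MEI synthesis possible downstream.

#' Model architecture configuration
#'
#' Layer 1: 16 space-time separable kernels 2 x 11 x 11 x 21 applied as valid
#' convolution (18 x 16 canvas -> 8 x 6 feature maps). Layer 2: 16 kernels
#' 16 x 5 x 5 x 11, zero-padded spatially, valid in time. Temporal kernels
#' are Fourier series (k = floor(length/3): 7 and 3 sine/cosine pairs) on a
#' \[0, 1\] grid, stretched per recording by a factor `tau` and masked by a
#' logistic envelope. Both layers use batch normalisation; the CNN uses ELU
#' activations, the LN variant the identity.
#'
#' @param activation "elu" (CNN) or "identity" (LN variant)
#' @param harmonics multiply the Fourier phase by the harmonic index j
#'   (`FALSE` reproduces the degenerate single-frequency form)
#' @param env_scale,env_len_factor constants of the logistic envelope
#'   `eps(tau) = 1 / (1 + exp(-(t + L * env_scale * tau)))`
#' @param train_tau learn the per-recording time-stretch factor
#' @return list of class `twin_arch`
#' @export
twin_arch <- function(activation = c("elu", "identity"), harmonics = TRUE,
                      env_scale = 0.95, env_len_factor = NULL,
                      train_tau = TRUE) {
  activation <- match.arg(activation)
  a <- list(F1 = 16L, F2 = 16L, L1 = 21L, L2 = 11L, k1 = 7L, k2 = 3L,
            ks1 = 11L, ks2 = 5L, H = CANVAS_H, W = CANVAS_W,
            Hc = CANVAS_H - 10L, Wc = CANVAS_W - 10L,
            activation = activation, harmonics = harmonics,
            env_scale = env_scale, train_tau = train_tau,
            bn_eps = 1e-4, bn_momentum = 0.1)
  stopifnot(a$k1 == floor(a$L1 / 3), a$k2 == floor(a$L2 / 3))
  class(a) <- "twin_arch"
  a
}

## ---- temporal kernels -----------------------------------------------------

## Fourier sine/cosine design matrices for a temporal kernel of length L with
## k harmonics, stretch tau, and the logistic envelope. Returns S, C [L x k]
## and their derivatives w.r.t. tau.
temporal_basis <- function(L, k, tau, harmonics = TRUE, env_scale = 0.95) {
  if (tau <= 0) stop("tau must be > 0")
  t <- seq(0, 1, length.out = L)
  z <- t + L * env_scale * tau
  env <- 1 / (1 + exp(-z))
  denv <- env * (1 - env) * L * env_scale
  phase0 <- 2 * pi * tau * t * env
  dphase0 <- 2 * pi * t * (env + tau * denv)
  jf <- if (harmonics) seq_len(k) else rep(1, k)
  P <- outer(phase0, jf)              # [L x k]
  dP <- outer(dphase0, jf)
  list(S = sin(P), C = cos(P), dS = cos(P) * dP, dC = -sin(P) * dP)
}

#' Evaluate a Fourier-parameterised temporal kernel
#'
#' `w = sum_j alpha_j sin(2 pi j tau t eps(tau)) + beta_j cos(...)` on an
#' evenly spaced grid t in \[0, 1\] of the kernel length, with the logistic
#' envelope `eps`.
#'
#' @param alpha,beta Fourier weights, length-k vectors (or `[k x F]` matrices
#'   for F kernels)
#' @param L kernel length in frames
#' @param tau time-stretch factor (> 0)
#' @param harmonics,env_scale see [twin_arch()]
#' @return kernel vector of length L (or `[L x F]` matrix)
#' @export
temporal_kernel <- function(alpha, beta, L, tau = 1, harmonics = TRUE,
                            env_scale = 0.95) {
  alpha <- as.matrix(alpha); beta <- as.matrix(beta)
  stopifnot(nrow(alpha) == nrow(beta))
  if (nrow(alpha) > floor(L / 3))
    stop("k exceeds floor(L/3): too many harmonics for this kernel length")
  b <- temporal_basis(L, nrow(alpha), tau, harmonics, env_scale)
  k <- b$S %*% alpha + b$C %*% beta
  if (ncol(k) == 1) as.numeric(k) else k
}

## ---- index tables ---------------------------------------------------------

build_widx1 <- function(a) {
  P <- a$Hc * a$Wc; E <- a$ks1^2 * N_CHAN
  widx <- matrix(0L, P, E)
  for (j in seq_len(a$Wc)) for (i in seq_len(a$Hc)) {
    p <- i + a$Hc * (j - 1L)
    e <- 0L
    for (ch in 0:(N_CHAN - 1L)) for (dx in 0:(a$ks1 - 1L))
      for (dy in 0:(a$ks1 - 1L)) {
        e <- e + 1L
        widx[p, e] <- (i + dy) + a$H * (j + dx - 1L) + a$H * a$W * ch
      }
  }
  widx
}

build_widx2 <- function(a) {
  P <- a$Hc * a$Wc; half <- (a$ks2 - 1L) %/% 2L
  E <- a$ks2^2 * a$F1
  widx <- matrix(0L, P, E)
  for (j in seq_len(a$Wc)) for (i in seq_len(a$Hc)) {
    p <- i + a$Hc * (j - 1L)
    e <- 0L
    for (f in seq_len(a$F1)) for (dx in -half:half) for (dy in -half:half) {
      e <- e + 1L
      ii <- i + dy; jj <- j + dx
      widx[p, e] <- if (ii >= 1 && ii <= a$Hc && jj >= 1 && jj <= a$Wc)
        ii + a$Hc * (jj - 1L) + a$Hc * a$Wc * (f - 1L) else 0L
    }
  }
  widx
}

## Input-canvas coordinates of the core output grid positions.
core_grid_coords <- function(a) {
  off <- (a$ks1 - 1L) / 2
  list(y = seq_len(a$Hc) + off, x = seq_len(a$Wc) + off)
}

## ---- initialisation -------------------------------------------------------

#' Initialise a digital-twin model
#'
#' @param n_neurons number of readouts
#' @param arch a [twin_arch()]
#' @param seed RNG seed for the weight initialisation
#' @param mean_rate mean target rate, used to initialise the readout bias so
#'   the softplus output starts near the data's operating point
#' @return object of class `twin_model`
#' @export
init_model <- function(n_neurons, arch = twin_arch(), seed = 0L,
                       mean_rate = 1) {
  set.seed(seed)
  a <- arch
  E1 <- a$ks1^2 * N_CHAN; E2 <- a$ks2^2 * a$F1
  N <- as.integer(n_neurons)
  params <- list(
    W1 = matrix(rnorm(E1 * a$F1, 0, 0.05), E1, a$F1),
    a1 = matrix(rnorm(a$k1 * a$F1, 0, 0.3), a$k1, a$F1),
    b1 = matrix(rnorm(a$k1 * a$F1, 0, 0.3), a$k1, a$F1),
    W2 = matrix(rnorm(E2 * a$F2, 0, 0.05), E2, a$F2),
    a2 = matrix(rnorm(a$k2 * a$F2, 0, 0.3), a$k2, a$F2),
    b2 = matrix(rnorm(a$k2 * a$F2, 0, 0.3), a$k2, a$F2),
    g1 = rep(1, a$F1), be1 = rep(0, a$F1),
    g2 = rep(1, a$F2), be2 = rep(0, a$F2),
    tau = 1,
    mu = rbind(x = (1 + a$W) / 2 + rnorm(N, 0, 0.5),
               y = (1 + a$H) / 2 + rnorm(N, 0, 0.5)),
    sig = rep(2.5, N),
    wf = matrix(rnorm(a$F2 * N, 0, 0.1), a$F2, N),
    b0 = rep(softplus_inv(mean_rate), N))
  state <- list(rm1 = rep(0, a$F1), rv1 = rep(1, a$F1),
                rm2 = rep(0, a$F2), rv2 = rep(1, a$F2))
  m <- list(arch = a, params = params, state = state,
            widx1 = build_widx1(a), widx2 = build_widx2(a),
            n_neurons = N, norm = NULL, trained = FALSE, seed = seed)
  class(m) <- "twin_model"
  m
}

## ---- temporal convolution (valid, per feature, via BLAS) ------------------

## Banded kernel matrix: Km[t, t'] = k[t - t' + 1].
tconv_kernel_matrix <- function(k, T) {
  L <- length(k); To <- T - L + 1L
  Km <- matrix(0, T, To)
  for (u in seq_len(L))
    Km[cbind(u:(u + To - 1L), seq_len(To))] <- k[u]
  Km
}

## A: [(M*B*T) x F] rows ordered (m, b, t); K: [L x F]. Valid conv in t.
tconv_fwd <- function(A, K, MB, T) {
  L <- nrow(K); To <- T - L + 1L; F <- ncol(K)
  out <- matrix(0, MB * To, F)
  for (f in seq_len(F))
    out[, f] <- matrix(A[, f], MB, T) %*% tconv_kernel_matrix(K[, f], T)
  out
}

tconv_bwd_input <- function(gO, K, MB, T) {
  L <- nrow(K); To <- T - L + 1L; F <- ncol(K)
  gA <- matrix(0, MB * T, F)
  for (f in seq_len(F))
    gA[, f] <- tcrossprod(matrix(gO[, f], MB, To),
                          tconv_kernel_matrix(K[, f], T))
  gA
}

tconv_bwd_kernel <- function(gO, A, MB, T, L) {
  To <- T - L + 1L; F <- ncol(A)
  gK <- matrix(0, L, F)
  for (f in seq_len(F)) {
    Mt <- crossprod(matrix(A[, f], MB, T), matrix(gO[, f], MB, To))
    for (u in seq_len(L))
      gK[u, f] <- sum(Mt[cbind(u:(u + To - 1L), seq_len(To))])
  }
  gK
}

## ---- batch norm -----------------------------------------------------------

scale_cols <- function(x, v) x * rep(v, each = nrow(x))
shift_cols <- function(x, v) x + rep(v, each = nrow(x))

bn_forward <- function(x, gamma, beta, eps, training, rm, rv) {
  if (training) {
    mu <- colMeans(x)
    xc <- shift_cols(x, -mu)
    v <- colMeans(xc^2)
    istd <- 1 / sqrt(v + eps)
    xhat <- scale_cols(xc, istd)
    y <- shift_cols(scale_cols(xhat, gamma), beta)
    list(y = y, xhat = xhat, istd = istd, mu = mu, var = v)
  } else {
    istd <- 1 / sqrt(rv + eps)
    xhat <- scale_cols(shift_cols(x, -rm), istd)
    y <- shift_cols(scale_cols(xhat, gamma), beta)
    list(y = y, xhat = xhat, istd = istd)
  }
}

bn_backward <- function(gy, cache, gamma, training) {
  ggamma <- colSums(gy * cache$xhat)
  gbeta <- colSums(gy)
  gxhat <- scale_cols(gy, gamma)
  if (training) {
    n <- nrow(gy)
    t1 <- colSums(gxhat)
    t2 <- colSums(gxhat * cache$xhat)
    gx <- shift_cols(gxhat, -t1 / n) -
      scale_cols(cache$xhat, t2 / n)
    gx <- scale_cols(gx, cache$istd)
  } else {
    gx <- scale_cols(gxhat, cache$istd)
  }
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

act_forward <- function(x, activation) {
  if (activation == "elu") elu(x) else x
}
act_backward <- function(gy, y, activation) {
  if (activation == "elu") {
    neg <- y < 0
    gy[neg] <- gy[neg] * (y[neg] + 1)  # d elu/dx = elu(x) + 1 for x < 0
  }
  gy
}

## ---- readout --------------------------------------------------------------

## Gaussian readout weights over the core grid: G [P x N].
readout_weights <- function(a, mu, sig) {
  gc <- core_grid_coords(a)
  P <- a$Hc * a$Wc; N <- ncol(mu)
  ys <- rep(gc$y, times = a$Wc); xs <- rep(gc$x, each = a$Hc)
  G <- matrix(0, P, N)
  for (n in seq_len(N)) {
    d2 <- (ys - mu["y", n])^2 + (xs - mu["x", n])^2
    G[, n] <- exp(-d2 / (2 * sig[n]^2)) / (2 * pi * sig[n]^2)
  }
  G
}

## ---- forward / backward ---------------------------------------------------

## Forward pass. x: [576 x T x B] z-scored stimulus chunks (pixel-major
## frames, green then UV). Intermediate rows are ordered (position, batch,
## time). Returns predictions y [N x B*(T-30)] with columns ordered b
## fastest, then t, and, if cache=TRUE, everything needed for backward.
twin_forward <- function(model, x, training = FALSE, cache = FALSE,
                         readout = NULL) {
  a <- model$arch; p <- model$params; st <- model$state
  d <- dim(x)
  if (is.null(d) || length(d) != 3 || d[1] != a$H * a$W * N_CHAN)
    stop("stimulus must be [", a$H * a$W * N_CHAN, " x T x B] (18 x 16 canvas)")
  T <- d[2]; B <- d[3]
  if (T < a$L1 + a$L2 - 1L)
    stop("chunk shorter than the total temporal support (",
         a$L1 + a$L2 - 1L, " frames)")
  M <- a$Hc * a$Wc
  b1 <- temporal_basis(a$L1, a$k1, p$tau, a$harmonics, a$env_scale)
  b2 <- temporal_basis(a$L2, a$k2, p$tau, a$harmonics, a$env_scale)
  K1 <- b1$S %*% p$a1 + b1$C %*% p$b1
  K2 <- b2$S %*% p$a2 + b2$C %*% p$b2

  P1 <- im2col_frames(as.numeric(x), model$widx1, d[1], T, B)
  S1 <- P1 %*% p$W1
  A1 <- tconv_fwd(S1, K1, M * B, T)
  T1 <- T - a$L1 + 1L
  bn1 <- bn_forward(A1, p$g1, p$be1, a$bn_eps, training, st$rm1, st$rv1)
  H1 <- act_forward(bn1$y, a$activation)

  ## reorder H1 rows (p,b,t) x f  ->  frame stack [(p,f) x t x b]
  H1a <- array(H1, dim = c(M, B, T1, a$F1))
  H1s <- aperm(H1a, c(1, 4, 3, 2))
  P2 <- im2col_frames(as.numeric(H1s), model$widx2, M * a$F1, T1, B)
  S2 <- P2 %*% p$W2
  A2 <- tconv_fwd(S2, K2, M * B, T1)
  T2 <- T1 - a$L2 + 1L
  bn2 <- bn_forward(A2, p$g2, p$be2, a$bn_eps, training, st$rm2, st$rv2)
  C <- act_forward(bn2$y, a$activation)

  ## a readout override (list with mu, sig, wf, b0) evaluates an arbitrary
  ## set of virtual neurons, e.g. readouts recentred on the canvas for MEI
  ## synthesis
  mu <- if (is.null(readout)) p$mu else readout$mu
  sig <- if (is.null(readout)) p$sig else readout$sig
  wf <- if (is.null(readout)) p$wf else readout$wf
  b0 <- if (is.null(readout)) p$b0 else readout$b0
  N <- ncol(mu)
  G <- readout_weights(a, mu, sig)
  Cm <- matrix(C, M, T2 * B * a$F2)
  V <- crossprod(G, Cm)                       # [N x T2*B*F2]
  Va <- array(V, dim = c(N, T2 * B, a$F2))
  pre <- matrix(0, N, T2 * B)
  for (n in seq_len(N))
    pre[n, ] <- Va[n, , ] %*% wf[, n] + b0[n]
  y <- softplus(pre)

  out <- list(y = y, pre = pre, T = T, T1 = T1, T2 = T2, B = B)
  if (training) {
    mom <- a$bn_momentum
    out$new_state <- list(
      rm1 = (1 - mom) * st$rm1 + mom * bn1$mu,
      rv1 = (1 - mom) * st$rv1 + mom * bn1$var,
      rm2 = (1 - mom) * st$rm2 + mom * bn2$mu,
      rv2 = (1 - mom) * st$rv2 + mom * bn2$var)
  }
  if (cache) {
    out$cache <- list(x = x, P1 = P1, S1 = S1, bn1 = bn1, H1 = H1,
                      H1s = H1s, P2 = P2, S2 = S2, bn2 = bn2, C = C,
                      G = G, Va = Va, K1 = K1, K2 = K2, basis1 = b1,
                      basis2 = b2, mu = mu, sig = sig, wf = wf,
                      training = training)
  }
  out
}

## Backward pass. gy: gradient of the objective w.r.t. the model output y
## [N x T2*B]. Returns parameter gradients and optionally the input gradient.
twin_backward <- function(model, fwd, gy, grad_input = FALSE) {
  a <- model$arch; p <- model$params; ch <- fwd$cache
  M <- a$Hc * a$Wc; T <- fwd$T; T1 <- fwd$T1; T2 <- fwd$T2; B <- fwd$B
  N <- nrow(gy)
  training <- ch$training

  gpre <- gy * sigmoid(fwd$pre)
  gb0 <- rowSums(gpre)
  gwf <- matrix(0, a$F2, N)
  gVa <- array(0, dim = c(N, T2 * B, a$F2))
  for (n in seq_len(N)) {
    gwf[, n] <- crossprod(ch$Va[n, , ], gpre[n, ])
    gVa[n, , ] <- outer(gpre[n, ], ch$wf[, n])
  }
  gVm <- matrix(gVa, N, T2 * B * a$F2)
  Cm <- matrix(ch$C, M, T2 * B * a$F2)
  gG <- Cm %*% t(gVm)                         # [M x N]
  gCm <- ch$G %*% gVm                         # [M x T2*B*F2]
  gC <- matrix(gCm, M * T2 * B, a$F2)

  ## readout location/size gradients
  gc <- core_grid_coords(a)
  ys <- rep(gc$y, times = a$Wc); xs <- rep(gc$x, each = a$Hc)
  gmu <- matrix(0, 2, N, dimnames = list(c("x", "y"), NULL))
  gsig <- numeric(N)
  for (n in seq_len(N)) {
    dx <- xs - ch$mu["x", n]; dy <- ys - ch$mu["y", n]
    s <- ch$sig[n]
    gmu["x", n] <- sum(gG[, n] * ch$G[, n] * dx / s^2)
    gmu["y", n] <- sum(gG[, n] * ch$G[, n] * dy / s^2)
    gsig[n] <- sum(gG[, n] * ch$G[, n] * ((dx^2 + dy^2) / s^3 - 2 / s))
  }

  gBn2 <- act_backward(gC, ch$C, a$activation)
  bw2 <- bn_backward(gBn2, ch$bn2, p$g2, training)
  gA2 <- bw2$gx
  gS2 <- tconv_bwd_input(gA2, ch$K2, M * B, T1)
  gK2 <- tconv_bwd_kernel(gA2, ch$S2, M * B, T1, a$L2)
  gW2 <- crossprod(ch$P2, gS2)
  gP2 <- tcrossprod(gS2, p$W2)
  gH1s <- col2im_frames(gP2, model$widx2, M * a$F1, T1, B)
  gH1 <- matrix(aperm(array(gH1s, dim = c(M, a$F1, T1, B)), c(1, 4, 3, 2)),
                M * T1 * B, a$F1)
  gBn1 <- act_backward(gH1, ch$H1, a$activation)
  bw1 <- bn_backward(gBn1, ch$bn1, p$g1, training)
  gA1 <- bw1$gx
  gS1 <- tconv_bwd_input(gA1, ch$K1, M * B, T)
  gK1 <- tconv_bwd_kernel(gA1, ch$S1, M * B, T, a$L1)
  gW1 <- crossprod(ch$P1, gS1)

  ga1 <- crossprod(ch$basis1$S, gK1); gb1 <- crossprod(ch$basis1$C, gK1)
  ga2 <- crossprod(ch$basis2$S, gK2); gb2 <- crossprod(ch$basis2$C, gK2)
  gtau <- 0
  if (a$train_tau) {
    dK1 <- ch$basis1$dS %*% p$a1 + ch$basis1$dC %*% p$b1
    dK2 <- ch$basis2$dS %*% p$a2 + ch$basis2$dC %*% p$b2
    gtau <- sum(gK1 * dK1) + sum(gK2 * dK2)
  }

  grads <- list(W1 = gW1, a1 = ga1, b1 = gb1, W2 = gW2, a2 = ga2, b2 = gb2,
                g1 = bw1$ggamma, be1 = bw1$gbeta,
                g2 = bw2$ggamma, be2 = bw2$gbeta,
                tau = gtau, mu = gmu, sig = gsig, wf = gwf, b0 = gb0)
  if (grad_input) {
    gP1 <- tcrossprod(gS1, p$W1)
    gx <- col2im_frames(gP1, model$widx1, a$H * a$W * N_CHAN, T, B)
    grads$x <- array(gx, dim = dim(ch$x))
  }
  grads
}

#' Poisson loss
#'
#' `sum(pred - target * log(pred))` over all neurons and time points.
#' @param pred predicted rates (> 0)
#' @param target observed rates (>= 0)
#' @return scalar loss
#' @export
poisson_loss <- function(pred, target) {
  if (any(pred <= 0)) stop("Poisson loss needs strictly positive predictions")
  sum(pred - target * log(pred))
}

## Gradient of the Poisson loss w.r.t. the prediction.
poisson_loss_grad <- function(pred, target) 1 - target / pred

#' Predict rates for a stimulus sequence
#'
#' Runs the model in evaluation mode (frozen batch-norm statistics) over a
#' full frame sequence, windowed to bound memory. With valid temporal
#' convolutions the prediction at output index t corresponds to input frame
#' t + 30.
#'
#' @param model a `twin_model` or `twin_ensemble`
#' @param frames_z z-scored frame matrix `[576 x T]`
#' @param window forward-window length in frames
#' @return matrix `[N x (T - 30)]` of predicted rates
#' @export
predict_rates <- function(model, frames_z, window = 620L) {
  if (inherits(model, "twin_ensemble")) {
    preds <- lapply(model$members, predict_rates, frames_z = frames_z,
                    window = window)
    return(Reduce(`+`, preds) / length(preds))
  }
  a <- model$arch
  sup <- a$L1 + a$L2 - 2L                # frames of history per output
  T <- ncol(frames_z)
  To <- T - sup
  if (To < 1) stop("sequence shorter than the temporal support")
  out <- matrix(0, model$n_neurons, To)
  s <- 1L
  while (s <= To) {
    e <- min(s + window - 1L, To)
    xin <- frames_z[, s:(e + sup), drop = FALSE]
    dim(xin) <- c(nrow(frames_z), ncol(xin), 1L)
    fw <- twin_forward(model, xin, training = FALSE)
    out[, s:e] <- fw$y
    s <- e + 1L
  }
  out
}
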