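## Maximally exciting inputs: synthesis by constrained gradient ascent on the
## trained model, and characterisation (SVD decomposition, DoG fits, centre
## size/mask, temporal frequency, chromatic contrast and opponency).

mei_default_opts <- function() {
  list(lr = 10, b = 30, max_iter = 1000L, min_iter = 100L,
       conv_tol = 0.001, conv_patience = 10L, seed = 0L, init_sd = 0.1)
}

#' Model response and input gradient for the MEI objective
#'
#' Evaluates the mean response over the optimisation window and its
#' gradient with respect to the input, for one neuron per stimulus in the
#' batch (ensemble members are averaged). With `centred = TRUE` the readout
#' location is moved to the canvas centre, as during MEI synthesis.
#'
#' @param model a trained `twin_model` or `twin_ensemble`
#' @param x stimulus array `[576 x 50 x B]` in z-score space
#' @param neurons neuron index per stimulus (length B, or length 1 reused)
#' @param centred evaluate with the readout recentred on the canvas
#' @return list with `act` (length-B activations) and `gx` (gradient array
#'   of the same shape as `x`)
#' @export
mei_objective <- function(model, x, neurons, centred = TRUE) {
  if (length(neurons) == 1L && dim(x)[3] > 1L)
    neurons <- rep(neurons, dim(x)[3])
  members <- if (inherits(model, "twin_ensemble")) model$members else list(model)
  B <- dim(x)[3]
  To <- dim(x)[2] - 30L
  act <- rep(0, length(neurons))
  gx <- array(0, dim = dim(x))
  for (mb in members) {
    mu <- mb$params$mu[, neurons, drop = FALSE]
    if (centred) {
      mu["x", ] <- (1 + mb$arch$W) / 2
      mu["y", ] <- (1 + mb$arch$H) / 2
    }
    ro <- list(mu = mu, sig = mb$params$sig[neurons],
               wf = mb$params$wf[, neurons, drop = FALSE],
               b0 = mb$params$b0[neurons])
    fw <- twin_forward(mb, x, training = FALSE, cache = TRUE, readout = ro)
    ## y is [n_sel x B*To] (columns b fastest); neuron j scores stimulus j
    ya <- array(fw$y, dim = c(length(neurons), B, To))
    act <- act + vapply(seq_along(neurons), function(j)
      mean(ya[j, j, ]), numeric(1))
    gy <- matrix(0, length(neurons), B * To)
    gya <- array(0, dim = c(length(neurons), B, To))
    for (j in seq_along(neurons)) gya[j, j, ] <- 1 / To
    gy[] <- gya
    gr <- twin_backward(mb, fw, gy, grad_input = TRUE)
    gx <- gx + gr$x
  }
  list(act = act / length(members), gx = gx / length(members))
}

#' Synthesise maximally exciting inputs for a set of model neurons
#'
#' Gradient ascent on the model neuron's response averaged over the
#' optimisation window (the last 20 of 50 frames, which is exactly the
#' valid output of a 50-frame input), with the readout location centred on
#' the canvas. After each step the stimulus is rescaled to the L2 norm
#' budget `b` jointly across both channels, then clipped per channel to the
#' z-scored range covered by the training movie. Optimisation runs at least
#' `min_iter` iterations and stops at `max_iter` or when the activation has
#' changed by less than `conv_tol` for `conv_patience` consecutive
#' iterations (per neuron; converged stimuli are frozen).
#'
#' @param model a trained `twin_model` or `twin_ensemble`
#' @param neurons integer vector of neuron indices
#' @param opts list overriding [synthesize defaults][mei_default_opts]:
#'   `lr` (10), `b` (30), `max_iter` (1000), `min_iter` (100), `conv_tol`
#'   (0.001), `conv_patience` (10), `seed`, `init_sd`
#' @return list of `mei_record` objects (tensor `[2 x 50 x 18 x 16]`,
#'   activation trace, convergence info, constraint provenance)
#' @export
synthesize_meis <- function(model, neurons, opts = list()) {
  o <- utils::modifyList(mei_default_opts(), opts)
  if (!(if (inherits(model, "twin_ensemble")) model$members[[1]]$trained
        else model$trained))
    stop("model must be trained before MEI synthesis")
  norm <- model$norm
  if (is.null(norm)) stop("model carries no stimulus normalisation")
  zr <- norm$zrange
  D <- CANVAS_H * CANVAS_W * N_CHAN
  np <- CANVAS_H * CANVAS_W
  B <- length(neurons)
  Tn <- 50L
  set.seed(o$seed)
  x <- array(rnorm(D * Tn * B, 0, o$init_sd), dim = c(D, Tn, B))

  project <- function(xs) {
    nr <- sqrt(sum(xs^2))
    xs <- xs * (o$b / nr)
    xs[seq_len(np), ] <- pmin(pmax(xs[seq_len(np), ], zr["green", "min"]),
                              zr["green", "max"])
    xs[np + seq_len(np), ] <- pmin(pmax(xs[np + seq_len(np), ],
                                        zr["uv", "min"]), zr["uv", "max"])
    xs
  }
  for (j in seq_len(B)) x[, , j] <- project(x[, , j])

  traces <- vector("list", B)
  frozen <- rep(FALSE, B)
  stable <- rep(0L, B)
  conv_iter <- rep(NA_integer_, B)
  last_act <- rep(NA_real_, B)
  it <- 0L
  while (it < o$max_iter && !all(frozen)) {
    it <- it + 1L
    ob <- mei_objective(model, x, neurons)
    if (any(!is.finite(ob$gx)))
      stop("NaN gradient in MEI synthesis at iteration ", it)
    for (j in seq_len(B)) {
      traces[[j]] <- c(traces[[j]], ob$act[j])
      if (frozen[j]) next
      x[, , j] <- project(x[, , j] + o$lr * ob$gx[, , j])
      if (!is.na(last_act[j]) && abs(ob$act[j] - last_act[j]) < o$conv_tol)
        stable[j] <- stable[j] + 1L else stable[j] <- 0L
      last_act[j] <- ob$act[j]
      if (it >= o$min_iter && stable[j] >= o$conv_patience) {
        frozen[j] <- TRUE
        conv_iter[j] <- it
      }
    }
  }
  lapply(seq_len(B), function(j) {
    tens <- array(0, dim = c(N_CHAN, Tn, CANVAS_H, CANVAS_W))
    tens[1, , , ] <- t(x[seq_len(np), , j])
    tens[2, , , ] <- t(x[np + seq_len(np), , j])
    rec <- list(tensor = tens, neuron = neurons[j],
                activation_trace = traces[[j]],
                converged = frozen[j], n_iter = it,
                conv_iter = conv_iter[j], b = o$b,
                window = c(31L, 50L), seed = o$seed, zrange = zr,
                norm = norm)
    class(rec) <- "mei_record"
    rec
  })
}

#' Synthesise the MEI of a single model neuron
#' @inheritParams synthesize_meis
#' @param neuron neuron index
#' @return a `mei_record`
#' @export
synthesize_mei <- function(model, neuron, opts = list()) {
  synthesize_meis(model, neuron, opts)[[1]]
}

#' L2 norm of an MEI tensor over both channels
#' @param mei a `mei_record` or tensor
#' @return scalar norm
#' @export
mei_norm <- function(mei) {
  tens <- if (inherits(mei, "mei_record")) mei$tensor else mei
  sqrt(sum(tens^2))
}

#' Decompose an MEI into spatial and temporal components per channel
#'
#' Singular value decomposition of the `[50 x 288]` flattened channel; the
#' temporal component is the first left singular vector, the spatial
#' component the first right singular vector reshaped to 18 x 16. The sign
#' is fixed so the spatial component is positive at its dominant pixel (the
#' effective receptive-field centre); the temporal component's sign follows.
#'
#' @param mei a `mei_record` (or bare tensor `[2 x 50 x 18 x 16]`)
#' @return object of class `mei_decomposition`: per channel `spatial`
#'   `[18 x 16]`, `temporal` `[50]`, `s1`, rank-1 reconstruction error and
#'   variance explained
#' @export
decompose_mei <- function(mei) {
  tens <- if (inherits(mei, "mei_record")) mei$tensor else mei
  chans <- c("green", "uv")
  out <- list()
  for (ci in 1:2) {
    m <- matrix(tens[ci, , , ], dim(tens)[2], dim(tens)[3] * dim(tens)[4])
    if (all(m == 0)) {
      out[[chans[ci]]] <- list(spatial = matrix(0, CANVAS_H, CANVAS_W),
                               temporal = rep(0, nrow(m)), s1 = 0,
                               recon_error = 0, var_explained = NA,
                               zero = TRUE)
      next
    }
    sv <- svd(m, nu = 1, nv = 1)
    u <- sv$u[, 1]; v <- sv$v[, 1]; s1 <- sv$d[1]
    if (v[which.max(abs(v))] < 0) { v <- -v; u <- -u }
    recon <- s1 * tcrossprod(u, v)
    out[[chans[ci]]] <- list(
      spatial = matrix(v, CANVAS_H, CANVAS_W),
      temporal = u, s1 = s1,
      recon_error = sqrt(sum((m - recon)^2)),
      var_explained = s1^2 / sum(sv$d^2), zero = FALSE)
  }
  structure(out, class = "mei_decomposition")
}

## ---- concentric anisotropic DoG fit ---------------------------------------

## Quadratic-form coefficients of a rotated anisotropic Gaussian.
gauss_coefs <- function(sx, sy, th) {
  list(f = cos(th)^2 / (2 * sx^2) + sin(th)^2 / (2 * sy^2),
       g = sin(2 * th) / 4 * (1 / sy^2 - 1 / sx^2),
       h = sin(th)^2 / (2 * sx^2) + cos(th)^2 / (2 * sy^2))
}

gauss2d <- function(X, Y, mux, muy, A, sx, sy, th) {
  cf <- gauss_coefs(sx, sy, th)
  dx <- X - mux; dy <- Y - muy
  A * exp(-(cf$f * dx^2 + 2 * cf$g * dx * dy + cf$h * dy^2))
}

## soft-L1 robust cost of residuals: sum(sqrt(1 + r^2) - 1)
soft_l1_cost <- function(r) sum(sqrt(1 + r^2) - 1)

#' Fit a concentric anisotropic difference-of-Gaussians to a spatial map
#'
#' Robust (soft-L1) nonlinear least squares of
#' `DoG = G_c - G_s`, two rotated anisotropic Gaussians sharing a centre
#' location. Initialisation: the centre starts at whichever of the map's
#' extrema lies closer to the canvas centre; a single Gaussian is fit first
#' and seeds the DoG fit. All parameters are bounded (centre inside the
#' canvas, strictly positive widths). Optimiser failures yield a flagged
#' record with infinite cost instead of an error.
#'
#' @param spatial numeric matrix `[18 x 16]`
#' @return object of class `dog_params`: `mu` (x, y in pixel coordinates),
#'   `A_c`, `A_s`, widths `sigma_c`, `sigma_s` (x, y), angles `theta_c`,
#'   `theta_s`, soft-L1 `cost`, and `fitted` surface
#' @export
fit_dog <- function(spatial) {
  stopifnot(is.matrix(spatial))
  if (sd(spatial) == 0) stop("spatial component is constant; cannot fit DoG")
  H <- nrow(spatial); W <- ncol(spatial)
  X <- matrix(rep(seq_len(W), each = H), H, W)
  Y <- matrix(rep(seq_len(H), W), H, W)
  ctr <- c((1 + W) / 2, (1 + H) / 2)
  imin <- which.min(spatial); imax <- which.max(spatial)
  pos <- function(i) c(X[i], Y[i])
  d2 <- function(pt) sum((pt - ctr)^2)
  start_pos <- if (d2(pos(imin)) < d2(pos(imax))) pos(imin) else pos(imax)
  A0 <- spatial[if (d2(pos(imin)) < d2(pos(imax))) imin else imax]

  amax <- 5 * max(abs(spatial))
  fit1 <- function(par) {
    r <- gauss2d(X, Y, par[1], par[2], par[3], par[4], par[5], par[6]) -
      spatial
    soft_l1_cost(r)
  }
  g0 <- c(start_pos[1], start_pos[2], A0, 2, 2, 0)
  lo1 <- c(1, 1, -amax, 0.3, 0.3, -pi)
  up1 <- c(W, H, amax, 12, 12, pi)
  o1 <- tryCatch(optim(g0, fit1, method = "L-BFGS-B", lower = lo1,
                       upper = up1, control = list(maxit = 200)),
                 error = function(e) NULL)
  p1 <- if (is.null(o1)) g0 else o1$par

  fit2 <- function(par) {
    mdl <- gauss2d(X, Y, par[1], par[2], par[3], par[5], par[6], par[9]) -
      gauss2d(X, Y, par[1], par[2], par[4], par[7], par[8], par[10])
    soft_l1_cost(mdl - spatial)
  }
  d0 <- c(p1[1], p1[2], p1[3], 0.1 * p1[3], p1[4], p1[5],
          2 * p1[4], 2 * p1[5], p1[6], p1[6])
  lo2 <- c(1, 1, -amax, -amax, 0.3, 0.3, 0.3, 0.3, -pi, -pi)
  up2 <- c(W, H, amax, amax, 12, 12, 18, 18, pi, pi)
  o2 <- tryCatch(optim(d0, fit2, method = "L-BFGS-B", lower = lo2,
                       upper = up2, control = list(maxit = 400)),
                 error = function(e) NULL)
  if (is.null(o2)) {
    out <- list(mu = c(x = NA, y = NA), failed = TRUE, cost = Inf)
    class(out) <- "dog_params"
    return(out)
  }
  par <- o2$par
  fitted <- gauss2d(X, Y, par[1], par[2], par[3], par[5], par[6], par[9]) -
    gauss2d(X, Y, par[1], par[2], par[4], par[7], par[8], par[10])
  out <- list(mu = c(x = par[1], y = par[2]),
              A_c = par[3], A_s = par[4],
              sigma_c = c(x = par[5], y = par[6]),
              sigma_s = c(x = par[7], y = par[8]),
              theta_c = par[9], theta_s = par[10],
              cost = o2$value, fitted = fitted, failed = FALSE,
              bounds = list(lower = lo2, upper = up2))
  class(out) <- "dog_params"
  out
}

#' MEI centre size from a DoG fit
#'
#' Centre diameters are `d_x = 2 sigma_x`, `d_y = 2 sigma_y`; the centre
#' size is their mean, `(sigma_x + sigma_y)` in pixels, converted with
#' `px_to_um`.
#'
#' @param dog a `dog_params`
#' @param px_to_um micrometres per stimulus pixel (default 6.25: a 100 um
#'   field over the 16-pixel canvas width; configurable because the
#'   simulated canvas has no physical scale of its own)
#' @return centre size in micrometres
#' @export
centre_size <- function(dog, px_to_um = 6.25) {
  stopifnot(inherits(dog, "dog_params"), !dog$failed)
  unname((dog$sigma_c["x"] + dog$sigma_c["y"]) * px_to_um)
}

#' Binary centre mask of a DoG fit
#'
#' The centre contour is the level set of the centre Gaussian at its value
#' at `(mu_x + sigma_x, mu_y + sigma_y)`; the mask contains all pixels
#' inside the convex hull of that contour (for a Gaussian the level set is
#' an ellipse, so this is the filled ellipse evaluated analytically).
#'
#' @param dog a `dog_params`
#' @return logical matrix `[18 x 16]`
#' @export
centre_mask <- function(dog) {
  stopifnot(inherits(dog, "dog_params"), !dog$failed)
  H <- CANVAS_H; W <- CANVAS_W
  X <- matrix(rep(seq_len(W), each = H), H, W)
  Y <- matrix(rep(seq_len(H), W), H, W)
  cf <- gauss_coefs(dog$sigma_c["x"], dog$sigma_c["y"], dog$theta_c)
  Q <- function(dx, dy) cf$f * dx^2 + 2 * cf$g * dx * dy + cf$h * dy^2
  q0 <- Q(dog$sigma_c["x"], dog$sigma_c["y"])
  mask <- Q(X - dog$mu["x"], Y - dog$mu["y"]) <= q0
  if (!any(mask)) {
    ## degenerate fit: single pixel at the centre, flagged
    mask <- matrix(FALSE, H, W)
    mask[round(pmin(pmax(dog$mu["y"], 1), H)),
         round(pmin(pmax(dog$mu["x"], 1), W))] <- TRUE
    attr(mask, "degenerate") <- TRUE
  }
  mask
}

#' Power-weighted mean temporal frequency of an MEI temporal component
#'
#' Low-pass filters the component (fifth-order Butterworth, 10 Hz cutoff),
#' then averages the FFT frequency components weighted by their relative
#' power.
#'
#' @param temporal numeric vector (50 frames)
#' @param frame_rate sampling rate in Hz
#' @param cutoff_hz Butterworth cutoff
#' @return frequency in Hz (0 with a flag for an all-zero input)
#' @export
temporal_frequency <- function(temporal, frame_rate = FRAME_RATE,
                               cutoff_hz = 10) {
  if (all(temporal == 0)) return(structure(0, flagged = TRUE))
  bf <- signal::butter(5, cutoff_hz / (frame_rate / 2), type = "low")
  filt <- signal::filtfilt(bf, temporal)
  n <- length(filt)
  pw <- Mod(fft(filt))^2
  keep <- seq_len(floor(n / 2) + 1L)
  freqs <- (keep - 1) * frame_rate / n
  sum(freqs * pw[keep]) / sum(pw[keep])
}

## Local maxima with a minimum prominence (fraction of the value range).
find_peaks <- function(v, min_prominence_frac = 0) {
  n <- length(v)
  if (n < 3) return(integer(0))
  cand <- which(diff(sign(diff(v))) < 0) + 1L
  thr <- min_prominence_frac * diff(range(v))
  keep <- vapply(cand, function(i) {
    l <- v[seq_len(i - 1L)]
    r <- v[(i + 1L):n]
    higher_l <- which(l > v[i])
    higher_r <- which(r > v[i])
    lmin <- if (length(higher_l)) min(l[(max(higher_l) + 1L):(i - 1L)])
            else min(l)
    rmin <- if (length(higher_r)) min(r[seq_len(min(higher_r) - 1L)])
            else min(r)
    (v[i] - max(lmin, rmin)) >= thr
  }, logical(1))
  cand[keep]
}

#' Chromatic contrast and opponency of an MEI
#'
#' Finds the peaks of the UV temporal component; the two last peaks define
#' time points t1 < t2, and the per-channel contrast is the difference of
#' the masked mean of the MEI at t2 minus t1 (the UV peaks are used for
#' both channels). Opponency means opposite contrast signs in the two
#' channels. t2 is the last *prominent* peak (prominence at least
#' `prominence_frac` of the component's range) and t1 the last local
#' maximum before it: frames after the final genuine peak are only weakly
#' constrained by the response window, and treating their residual ripples
#' as peaks would randomise the contrast.
#'
#' @param mei a `mei_record` or tensor `[2 x 50 x 18 x 16]`
#' @param decomp its [decompose_mei()] decomposition
#' @param mask logical centre mask `[18 x 16]` from [centre_mask()]
#' @param prominence_frac prominence (as a fraction of the component's
#'   range) a peak needs to qualify as t2; t1 peaks are unfiltered
#' @return list with `gamma` (named per-channel contrasts), `opponent`
#'   (logical), `chromatic_angle` (atan2(gamma_uv, gamma_green)), `t1`, `t2`
#' @export
mei_contrast <- function(mei, decomp, mask, prominence_frac = 0.05) {
  tens <- if (inherits(mei, "mei_record")) mei$tensor else mei
  pk_all <- find_peaks(decomp$uv$temporal, 0)
  pk_prom <- find_peaks(decomp$uv$temporal, prominence_frac)
  if (length(pk_prom) < 1 || !any(pk_all < max(pk_prom)))
    stop("fewer than 2 peaks in the UV temporal component; cell flagged")
  t2 <- max(pk_prom)
  t1 <- max(pk_all[pk_all < t2])
  mm <- function(ci, t) mean(tens[ci, t, , ][mask])
  gamma <- c(green = mm(1, t2) - mm(1, t1), uv = mm(2, t2) - mm(2, t1))
  list(gamma = gamma, opponent = sign(gamma[1]) != sign(gamma[2]),
       chromatic_angle = atan2(gamma["uv"], gamma["green"]),
       t1 = t1, t2 = t2)
}

#' Full property characterisation of one MEI
#'
#' Convenience wrapper: decomposition, per-channel DoG fits, centre size and
#' mask (UV channel mask by default, matching the contrast definition),
#' temporal frequencies, chromatic contrast and opponency.
#'
#' @param mei a `mei_record`
#' @param px_to_um pixel scale for centre size
#' @param mask_channel channel whose DoG defines the centre mask
#' @return list of class `mei_properties` (with `ok = FALSE` and a `reason`
#'   when a step flags the cell for exclusion)
#' @export
mei_properties <- function(mei, px_to_um = 6.25,
                           mask_channel = c("uv", "green")) {
  mask_channel <- match.arg(mask_channel)
  dec <- decompose_mei(mei)
  dogs <- lapply(c(green = "green", uv = "uv"), function(ch) {
    tryCatch(fit_dog(dec[[ch]]$spatial),
             error = function(e) structure(list(failed = TRUE, cost = Inf),
                                           class = "dog_params"))
  })
  res <- list(decomposition = dec, dog = dogs,
              dog_cost = c(green = dogs$green$cost, uv = dogs$uv$cost))
  if (dogs[[mask_channel]]$failed) {
    res$ok <- FALSE; res$reason <- "dog_fit_failed"
    class(res) <- "mei_properties"
    return(res)
  }
  msk <- centre_mask(dogs[[mask_channel]])
  res$mask <- msk
  res$centre_size <- vapply(dogs, function(d)
    if (d$failed) NA_real_ else centre_size(d, px_to_um), numeric(1))
  res$temporal_frequency <- c(
    green = as.numeric(temporal_frequency(dec$green$temporal)),
    uv = as.numeric(temporal_frequency(dec$uv$temporal)))
  ctr <- tryCatch(mei_contrast(mei, dec, msk), error = function(e) NULL)
  if (is.null(ctr)) {
    res$ok <- FALSE; res$reason <- "too_few_uv_peaks"
  } else {
    res$gamma <- ctr$gamma
    res$opponent <- ctr$opponent
    res$chromatic_angle <- ctr$chromatic_angle
    res$peak_times <- c(ctr$t1, ctr$t2)
    res$ok <- TRUE
  }
  class(res) <- "mei_properties"
  res
}
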