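## Chromatic-contrast tuning: responses and gradients of a model neuron on
## the 2-D subspace spanned by contrast-scaled green and UV MEI components.

#' Build the chromatic-contrast basis from an MEI
#'
#' `e1` is the green component of the MEI in the green channel multiplied by
#' -1 (zeros in UV); `e2` is the UV component in the UV channel (zeros in
#' green). The scale factors `s1`, `s2` equalise the per-channel L2 norms
#' while preserving the whole-stimulus contrast: both channel norms become
#' `sqrt((|g|^2 + |u|^2) / 2)`, so the stimulus at basis point (-1, 1) -- a
#' contrast-scaled version of the MEI -- has the MEI's total L2 norm.
#'
#' @param mei a `mei_record` or tensor `[2 x 50 x 18 x 16]`
#' @return list of class `contrast_basis`: tensors `e1`, `e2`, scalars
#'   `s1`, `s2`
#' @export
build_basis <- function(mei) {
  tens <- if (inherits(mei, "mei_record")) mei$tensor else mei
  g <- tens[1, , , ]; u <- tens[2, , , ]
  ng <- sqrt(sum(g^2)); nu <- sqrt(sum(u^2))
  if (ng == 0 || nu == 0) stop("both channels must be non-zero")
  target <- sqrt((ng^2 + nu^2) / 2)
  s1 <- target / ng; s2 <- target / nu
  e1 <- array(0, dim = dim(tens)); e2 <- array(0, dim = dim(tens))
  e1[1, , , ] <- -s1 * g
  e2[2, , , ] <- s2 * u
  structure(list(e1 = e1, e2 = e2, s1 = s1, s2 = s2),
            class = "contrast_basis")
}

#' Stimulus at a point of the contrast basis
#' @param basis a `contrast_basis`
#' @param a,b coefficients along `e1` (green contrast) and `e2` (UV contrast)
#' @return tensor `[2 x 50 x 18 x 16]`
#' @export
basis_stimulus <- function(basis, a, b) a * basis$e1 + b * basis$e2

#' Map a model neuron's chromatic-contrast tuning
#'
#' Evaluates the model neuron (readout centred, frozen normalisation) on an
#' `n x n` grid of basis coefficients equally spaced in \[-1, 1\]^2 -- the
#' original MEI sits at (-1, 1) -- and records the response plus the model
#' gradient projected onto the basis (`d response / d a = <grad, e1>`,
#' likewise for b).
#'
#' @param model trained `twin_model` or `twin_ensemble`
#' @param neuron neuron index
#' @param basis a [build_basis()] result
#' @param n grid points per axis
#' @param batch stimuli per forward pass (memory bound)
#' @return list of class `tuning_map`: `coef` (grid values), `response`
#'   (raw), `response_pct` (percent of max), `grad_a`, `grad_b`
#' @export
map_tuning <- function(model, neuron, basis, n = 11L, batch = 16L) {
  coef <- seq(-1, 1, length.out = n)
  pts <- expand.grid(a = coef, b = coef)
  D <- CANVAS_H * CANVAS_W * N_CHAN
  Tn <- dim(basis$e1)[2]
  to_mat <- function(tens) {
    np <- CANVAS_H * CANVAS_W
    m <- matrix(0, D, Tn)
    m[seq_len(np), ] <- t(matrix(tens[1, , , ], Tn, np))
    m[np + seq_len(np), ] <- t(matrix(tens[2, , , ], Tn, np))
    m
  }
  e1m <- to_mat(basis$e1); e2m <- to_mat(basis$e2)
  resp <- numeric(nrow(pts)); ga <- numeric(nrow(pts)); gb <- numeric(nrow(pts))
  i <- 1L
  while (i <= nrow(pts)) {
    j <- min(i + batch - 1L, nrow(pts))
    idx <- i:j
    x <- array(0, dim = c(D, Tn, length(idx)))
    for (k in seq_along(idx))
      x[, , k] <- pts$a[idx[k]] * e1m + pts$b[idx[k]] * e2m
    ob <- mei_objective(model, x, rep(neuron, length(idx)))
    resp[idx] <- ob$act
    for (k in seq_along(idx)) {
      ga[idx[k]] <- sum(ob$gx[, , k] * e1m)
      gb[idx[k]] <- sum(ob$gx[, , k] * e2m)
    }
    i <- j + 1L
  }
  rmax <- max(resp)
  structure(list(coef = coef,
                 response = matrix(resp, n, n),
                 response_pct = matrix(100 * resp / rmax, n, n),
                 grad_a = matrix(ga, n, n), grad_b = matrix(gb, n, n),
                 neuron = neuron),
            class = "tuning_map")
}
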