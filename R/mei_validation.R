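## In-silico validation of MEIs: rank-1 reconstruction as presentable
## stimuli, the 5 x 5 grid presentation experiment, spatially weighted
## responses, the selectivity index, and the inter-setup cone-activation
## calibration transform.

#' Reconstruct an MEI as a rank-1 stimulus tensor
#'
#' Per channel, the outer product `S11 * temporal %o% spatial`. With
#' `display = TRUE` the z-scored tensor is mapped to stimulator units by
#' scaling with the movie's SD and adding its mean (per channel), then to
#' the \[0, 255\] display range.
#'
#' @param decomp a [decompose_mei()] result
#' @param norm stimulus normalisation (`model$norm`), required for display
#'   mapping
#' @param display return stimulator units in \[0, 255\] instead of z-scores
#' @return tensor `[2 x 50 x 18 x 16]`
#' @export
reconstruct_rank1 <- function(decomp, norm = NULL, display = FALSE) {
  Tn <- length(decomp$green$temporal)
  out <- array(0, dim = c(N_CHAN, Tn, CANVAS_H, CANVAS_W))
  chans <- c("green", "uv")
  for (ci in 1:2) {
    d <- decomp[[chans[ci]]]
    m <- d$s1 * tcrossprod(d$temporal, as.numeric(d$spatial))
    out[ci, , , ] <- array(m, dim = c(Tn, CANVAS_H, CANVAS_W))
  }
  if (display) {
    if (is.null(norm)) stop("display mapping needs the movie normalisation")
    for (ci in 1:2)
      out[ci, , , ] <- out[ci, , , ] * norm$sd[ci] + norm$mean[ci]
    out <- pmin(pmax(out * 255, 0), 255)
  }
  out
}

#' Inter-setup chromatic calibration
#'
#' Relative M/S-cone activation matrices of the imaging setup (A) and the
#' electrophysiology setup (B). A stimulus `x` shown on setup A is matched
#' on setup B by `x' = B^-1 A x` (equal cone activation: `A x = B x'`).
#' @return list with matrices `A`, `B`
#' @export
setup_calibration <- function() {
  list(A = matrix(c(1, 0, 0.19, 1), 2, 2),
       B = matrix(c(1, 0.035, 0.9, 1), 2, 2))
}

#' Transform a stimulus between stimulation setups
#'
#' Applies `x' = B^-1 A x` per pixel/frame. With `restore_range = TRUE` the
#' result is affinely mapped (offset plus scalar gain) into \[0, 255\].
#'
#' @param x length-2 vector (green, UV) or 2-channel tensor with the channel
#'   as first dimension
#' @param cal list with 2 x 2 matrices `A`, `B` (default: [setup_calibration()])
#' @param restore_range affinely restore the display range
#' @return transformed stimulus of the same shape
#' @export
setup_transform <- function(x, cal = setup_calibration(),
                            restore_range = FALSE) {
  if (abs(det(cal$B)) < 1e-12) stop("setup matrix B is singular")
  M <- solve(cal$B) %*% cal$A
  if (is.null(dim(x))) {
    stopifnot(length(x) == 2)
    out <- as.numeric(M %*% x)
  } else {
    d <- dim(x)
    stopifnot(d[1] == 2)
    flat <- matrix(x, 2, prod(d[-1]))
    out <- array(M %*% flat, dim = d)
  }
  if (restore_range) {
    out <- out - min(out)
    if (max(out) > 0) out <- out * (255 / max(out))
  }
  out
}

#' Spatially weighted response to grid-presented stimuli
#'
#' Weights a cell's responses at each grid location by the Gaussian density
#' of its (model-estimated) receptive field at that location, sums over the
#' grid (weights are not renormalised; the plain weighted sum as defined),
#' and averages over the optimisation time window to give one scalar per
#' stimulus.
#'
#' @param responses array `[stimulus x gx x gy x time]` of (z-scored)
#'   responses at 30 Hz
#' @param grid_x,grid_y coordinates of the grid nodes (same units as `mu`)
#' @param mu length-2 named vector (x, y): readout location
#' @param sigma readout SD (> 0)
#' @param window time-average window (frames), default the optimisation
#'   window 31:50
#' @return numeric vector: one weighted scalar response per stimulus
#' @export
weighted_response <- function(responses, grid_x, grid_y, mu, sigma,
                              window = 31:50) {
  if (sigma <= 0) stop("sigma must be > 0")
  d <- dim(responses)
  stopifnot(length(d) == 4, d[2] == length(grid_x), d[3] == length(grid_y))
  wx <- outer(grid_x - mu[["x"]], grid_y - mu[["y"]],
              function(dx, dy) exp(-(dx^2 + dy^2) / (2 * sigma^2)) /
                (2 * pi * sigma^2))
  window <- window[window <= d[4]]
  vapply(seq_len(d[1]), function(s) {
    wt <- vapply(window, function(t) sum(responses[s, , , t] * wx),
                 numeric(1))
    mean(wt)
  }, numeric(1))
}

#' Selectivity index
#'
#' Standardises the per-stimulus responses (zero mean, unit SD across the
#' stimulus set) and returns the standardized response to the cell's own
#' MEI minus the mean standardized response to all other MEIs.
#'
#' @param rtilde numeric vector of weighted responses, one per MEI stimulus
#' @param own_index index of the cell's own group MEI
#' @return SI in units of SD response (0 with a flag if the responses have
#'   zero SD)
#' @export
selectivity_index <- function(rtilde, own_index) {
  stopifnot(length(rtilde) >= 2, own_index >= 1,
            own_index <= length(rtilde))
  s <- sd(rtilde)
  if (s == 0) return(structure(0, flagged = TRUE))
  z <- (rtilde - mean(rtilde)) / s
  unname(z[own_index] - mean(z[-own_index]))
}

#' Simulate the 5 x 5 grid MEI-presentation experiment on ground-truth cells
#'
#' Each rank-1 MEI stimulus is presented at a grid of spatial offsets around
#' the canvas centre (50 frames of stimulus padded after with 10 frames of
#' inter-stimulus grey), and ground-truth responses of the simulated cells
#' are recorded. Stimuli are built in z-score space, shifted spatially, and
#' converted to intensity with the movie normalisation before presentation.
#'
#' @param cells list of `simulated_cell`
#' @param rank1_stimuli list of z-scored rank-1 tensors `[2 x 50 x 18 x 16]`
#' @param norm stimulus normalisation (mean/SD per channel)
#' @param grid_offsets integer pixel offsets of the 5 x 5 grid along each
#'   axis (default -4, -2, 0, 2, 4)
#' @param grey_frames frames of grey appended after the stimulus
#' @return list with `responses` `[cell x stimulus x gx x gy x time]`,
#'   z-scored per cell over the experiment, plus grid coordinates in pixels
#' @export
simulate_grid_experiment <- function(cells, rank1_stimuli, norm,
                                     grid_offsets = seq(-4, 4, by = 2),
                                     grey_frames = 10L) {
  ng <- length(grid_offsets)
  S <- length(rank1_stimuli)
  Tn <- dim(rank1_stimuli[[1]])[2] + grey_frames
  N <- length(cells)
  resp <- array(0, dim = c(N, S, ng, ng, Tn))
  np <- CANVAS_H * CANVAS_W
  shift2d <- function(m, dy, dx) {
    out <- matrix(0, nrow(m), ncol(m))
    ys <- seq_len(nrow(m)); xs <- seq_len(ncol(m))
    yi <- ys - dy; xi <- xs - dx
    ok_y <- yi >= 1 & yi <= nrow(m); ok_x <- xi >= 1 & xi <= ncol(m)
    out[ys[ok_y], xs[ok_x]] <- m[yi[ok_y], xi[ok_x]]
    out
  }
  for (s in seq_len(S)) {
    base <- rank1_stimuli[[s]]
    for (ix in seq_len(ng)) for (iy in seq_len(ng)) {
      tens <- array(0, dim = c(2, Tn, CANVAS_H, CANVAS_W))
      for (ci in 1:2) {
        for (t in seq_len(dim(base)[2]))
          tens[ci, t, , ] <- shift2d(base[ci, t, , ],
                                     grid_offsets[iy], grid_offsets[ix]) *
            norm$sd[ci] + norm$mean[ci]
        tens[ci, (dim(base)[2] + 1):Tn, , ] <- norm$mean[ci]
      }
      fm <- movie_frame_matrix(tens)
      for (n in seq_len(N))
        resp[n, s, ix, iy, ] <- cell_response(cells[[n]], fm)
    }
  }
  for (n in seq_len(N)) {
    v <- resp[n, , , , ]
    if (sd(v) > 0) resp[n, , , , ] <- (v - mean(v)) / sd(v)
  }
  ctr <- c((1 + CANVAS_W) / 2, (1 + CANVAS_H) / 2)
  list(responses = resp, grid_x = ctr[1] + grid_offsets,
       grid_y = ctr[2] + grid_offsets, grid_offsets = grid_offsets)
}
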