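## Detection of ground-to-sky visual context changes: inter-clip transition
## contrasts, per-cell transition responses, ROC/AUC analysis, group tuning
## maps over chromatic contrast, and the moving-window transition-stimulus
## simulator.

#' Find inter-clip transitions of a movie
#'
#' One event per adjacent clip pair in the presentation sequence. The
#' transition contrast per channel is the mean full-field luminance over the
#' first second of the post-transition clip minus the mean over the last
#' second of the pre-transition clip ("michelson" uses the normalised
#' difference instead). `t0` is the last frame of the pre-transition clip.
#'
#' @param movie a `movie_stimulus`
#' @param window_s luminance-averaging window in seconds
#' @param contrast "difference" (default) or "michelson"
#' @return data.frame with `t0`, `pre_clip`, `post_clip`, `type`
#'   (e.g. "ground-to-sky"), `gamma_green`, `gamma_uv`
#' @export
find_transitions <- function(movie, window_s = 1,
                             contrast = c("difference", "michelson")) {
  contrast <- match.arg(contrast)
  ids <- movie$clip_ids
  bnd <- which(diff(ids) != 0)
  w <- round(window_s * movie$frame_rate)
  fm <- movie_frame_matrix(movie)
  np <- CANVAS_H * CANVAS_W
  lum_g <- colMeans(fm[seq_len(np), , drop = FALSE])
  lum_u <- colMeans(fm[np + seq_len(np), , drop = FALSE])
  lab <- movie$clip_labels
  out <- lapply(bnd, function(t0) {
    pre <- (t0 - w + 1L):t0
    post <- (t0 + 1L):(t0 + w)
    gg <- mean(lum_g[post]) - mean(lum_g[pre])
    gu <- mean(lum_u[post]) - mean(lum_u[pre])
    if (contrast == "michelson") {
      gg <- gg / (mean(lum_g[post]) + mean(lum_g[pre]))
      gu <- gu / (mean(lum_u[post]) + mean(lum_u[pre]))
    }
    data.frame(t0 = t0,
               pre_clip = ids[t0], post_clip = ids[t0 + 1L],
               type = paste0(lab[as.character(ids[t0])], "-to-",
                             lab[as.character(ids[t0 + 1L])]),
               gamma_green = gg, gamma_uv = gu)
  })
  do.call(rbind, out)
}

#' Baseline-subtracted transition response
#'
#' Mean response over the `T` frames following the transition minus the
#' response at the transition frame: `mean(r[t0+1 .. t0+T]) - r[t0]`.
#'
#' @param rate rate vector at 30 Hz
#' @param t0 transition frame index
#' @param T window length in frames (1 s at 30 Hz)
#' @return scalar response
#' @export
transition_response <- function(rate, t0, T = 30L) {
  if (t0 + T > length(rate) || t0 < 1)
    stop("response window exceeds the recording")
  mean(rate[(t0 + 1L):(t0 + T)]) - rate[t0]
}

#' ROC analysis of transition detection
#'
#' Sweeps `n_thresholds` equally spaced thresholds over the cell's response
#' range (both classes pooled), classifying above-threshold responses as the
#' target class, and integrates TPR over FPR by the trapezoid rule with
#' endpoints (0,0) and (1,1) appended.
#'
#' @param responses per-event scalar responses
#' @param labels logical, `TRUE` for target-class events
#' @param n_thresholds number of thresholds
#' @return list of class `roc_result`: `thresholds`, `fpr`, `tpr`, `auc`
#' @export
roc_auc <- function(responses, labels, n_thresholds = 40L) {
  labels <- as.logical(labels)
  stopifnot(length(responses) == length(labels))
  if (!any(labels) || all(labels))
    stop("ROC needs both a target and a non-target class")
  thr <- seq(min(responses), max(responses), length.out = n_thresholds)
  tpr <- vapply(thr, function(d) mean(responses[labels] > d), numeric(1))
  fpr <- vapply(thr, function(d) mean(responses[!labels] > d), numeric(1))
  ## sweep from high to low threshold: fpr/tpr increase monotonically
  ord <- order(fpr, tpr)
  fx <- c(0, fpr[ord], 1); fy <- c(0, tpr[ord], 1)
  auc <- sum(diff(fx) * (utils::head(fy, -1) + utils::tail(fy, -1)) / 2)
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_result")
}

#' Per-cell ground-to-sky detection performance on movie transitions
#'
#' @param events a [find_transitions()] table
#' @param rates matrix `[neuron x frames]` at 30 Hz
#' @param target transition type counted as positive
#' @param T response window (frames)
#' @return data.frame with per-cell AUC and the per-event response matrix as
#'   attribute `responses`
#' @export
detection_auc <- function(events, rates, target = "ground-to-sky", T = 30L) {
  keep <- events$t0 + T <= ncol(rates)
  events <- events[keep, ]
  resp <- t(vapply(seq_len(nrow(rates)), function(n)
    vapply(events$t0, function(t0) transition_response(rates[n, ], t0, T),
           numeric(1)), numeric(nrow(events))))
  lab <- events$type == target
  auc <- vapply(seq_len(nrow(rates)), function(n)
    roc_auc(resp[n, ], lab)$auc, numeric(1))
  out <- data.frame(neuron = seq_len(nrow(rates)), auc = auc)
  attr(out, "responses") <- resp
  attr(out, "labels") <- lab
  out
}

## ---- simulated transition stimuli ----------------------------------------

#' Generate a synthetic sky/ground scene
#'
#' A two-channel scene split by a horizon: the upper (sky) half has a higher
#' UV than green mean, the lower (ground) half the reverse, with low-pass
#' spatial texture. Dimensions default to the moving-window trajectory
#' (220-pixel edges plus the 72 x 64 window).
#'
#' @param seed integer seed
#' @param height,width scene size in pixels
#' @param mean_range range from which region means are drawn
#' @param texture_amp,texture_sigma_px texture SD and smoothing scale
#' @return list with `scene` array `[2 x height x width]` and `horizon` row
#' @export
generate_scene <- function(seed = 0L, height = 292L, width = 284L,
                           mean_range = c(0.04, 0.22), texture_amp = 0.05,
                           texture_sigma_px = 6) {
  set.seed(seed)
  lo <- runif(2, mean_range[1], mean_range[1] + 0.06)
  hi <- runif(2, mean_range[2] - 0.06, mean_range[2])
  sky <- c(green = lo[1], uv = hi[1])
  ground <- c(green = hi[2], uv = lo[2])
  horizon <- height %/% 2L
  scene <- array(0, dim = c(2, height, width))
  for (ci in 1:2) {
    tex <- texture_amp * clip_texture(1L, height, width,
                                      texture_sigma_px, 0)[1, , ]
    base <- matrix(0, height, width)
    base[seq_len(horizon), ] <- c(sky["green"], sky["uv"])[ci]
    base[(horizon + 1L):height, ] <- c(ground["green"], ground["uv"])[ci]
    scene[ci, , ] <- pmin(pmax(base + tex, 0), 1)
  }
  list(scene = scene, horizon = horizon, sky = sky, ground = ground)
}

## 4x4 block average of a [72 x 64] crop -> [18 x 16].
downsample_crop <- function(m, factor = 4L) {
  h <- nrow(m) %/% factor; w <- ncol(m) %/% factor
  a <- array(m[seq_len(h * factor), seq_len(w * factor)],
             dim = c(factor, h, factor, w))
  apply(a, c(2, 4), mean)
}

#' Angular-velocity to pixel-shift conversion
#'
#' The square trajectory's edges are 220 pixels, covering 90.6 degrees of
#' visual angle; at 30 Hz a velocity v deg/s moves
#' `round(v / 30 * 220 / 90.6)` pixels per frame.
#' @param velocity angular velocity in deg/s
#' @param frame_rate frames per second
#' @return pixels per frame (integer)
#' @export
px_per_frame <- function(velocity, frame_rate = FRAME_RATE) {
  as.integer(round(velocity / frame_rate * 220 / 90.6))
}

#' Simulate moving-window transition stimuli
#'
#' Slides a 72 x 64 window along a fixed square trajectory with 220-pixel
#' edges over a sky/ground scene, at one of four angular velocities,
#' downsampling each crop to 18 x 16 and padding with duplicated first/last
#' frames to 60 frames per edge traversal. Horizontal edges stay within one
#' region (no context change); vertical edges cross the horizon (context
#' change). Clockwise and counterclockwise directions traverse the same
#' positions in opposite order.
#'
#' @param scene a [generate_scene()] result
#' @param velocity angular velocity, one of 50, 150, 250, 350 deg/s (other
#'   values need `free_velocity = TRUE`)
#' @param direction "clockwise" or "counterclockwise"
#' @param free_velocity allow non-standard velocities
#' @return list of four `transition_stimulus` objects (frames
#'   `[2 x 60 x 18 x 16]`, `transition_type`, `t0` = frame nearest the
#'   horizon crossing or mid-traversal, `velocity`, `px_per_frame`,
#'   `direction`)
#' @export
simulate_transitions <- function(scene, velocity,
                                 direction = c("clockwise",
                                               "counterclockwise"),
                                 free_velocity = FALSE) {
  direction <- match.arg(direction)
  if (!free_velocity && !velocity %in% c(50, 150, 250, 350))
    stop("velocity must be one of 50, 150, 250, 350 deg/s")
  ppf <- px_per_frame(velocity)
  wh <- 72L; ww <- 64L; edge <- 220L
  sc <- scene$scene
  stopifnot(dim(sc)[2] >= edge + wh, dim(sc)[3] >= edge + ww)
  steps <- seq(0L, edge, by = ppf)
  ## top-left window positions along the four clockwise edges
  edges <- list(
    list(pos = cbind(1L, 1L + steps), type = "sky-to-sky"),
    list(pos = cbind(1L + steps, 1L + edge), type = "sky-to-ground"),
    list(pos = cbind(1L + edge, 1L + edge - steps), type = "ground-to-ground"),
    list(pos = cbind(1L + edge - steps, 1L), type = "ground-to-sky"))
  if (direction == "counterclockwise") {
    edges <- rev(edges)
    edges <- lapply(edges, function(e) {
      e$pos <- e$pos[rev(seq_len(nrow(e$pos))), , drop = FALSE]
      e$type <- switch(e$type,
                       "sky-to-ground" = "ground-to-sky",
                       "ground-to-sky" = "sky-to-ground",
                       e$type)
      e
    })
  }
  lapply(edges, function(e) {
    n <- nrow(e$pos)
    pad_front <- (60L - n) %/% 2L
    pad_back <- 60L - n - pad_front
    frames <- array(0, dim = c(2, 60L, CANVAS_H, CANVAS_W))
    for (k in seq_len(n)) {
      r <- e$pos[k, 1]; cc <- e$pos[k, 2]
      for (ci in 1:2)
        frames[ci, pad_front + k, , ] <-
          downsample_crop(sc[ci, r:(r + wh - 1L), cc:(cc + ww - 1L)])
    }
    for (k in seq_len(pad_front)) frames[, k, , ] <- frames[, pad_front + 1L, , ]
    if (pad_back > 0)
      for (k in (pad_front + n + 1L):60L) frames[, k, , ] <-
          frames[, pad_front + n, , ]
    crossing <- e$type %in% c("sky-to-ground", "ground-to-sky")
    t0 <- if (crossing) {
      centre_rows <- e$pos[, 1] + wh / 2
      pad_front + which.min(abs(centre_rows - scene$horizon))
    } else pad_front + n %/% 2L
    structure(list(frames = frames, velocity = velocity,
                   px_per_frame = ppf, direction = direction,
                   transition_type = e$type, t0 = as.integer(t0),
                   n_moving = n),
              class = "transition_stimulus")
  })
}

#' Simulated-transition detection performance per cell
#'
#' Presents moving-window transition stimuli from several random scenes (both
#' directions) to ground-truth cells and computes per-cell ground-to-sky
#' detection AUC per velocity.
#'
#' @param cells list of `simulated_cell`
#' @param velocities angular velocities to test
#' @param n_scenes random scenes per velocity
#' @param seed integer seed
#' @return data.frame with `velocity`, `neuron`, `family`, `auc`
#' @export
simulated_detection <- function(cells, velocities = c(50, 150, 250, 350),
                                n_scenes = 10L, seed = 0L) {
  out <- list()
  for (v in velocities) {
    resp <- list(); lab <- c()
    for (s in seq_len(n_scenes)) {
      sc <- generate_scene(seed = seed + 1000L * s)
      for (dir in c("clockwise", "counterclockwise")) {
        stims <- simulate_transitions(sc, v, dir)
        for (st in stims) {
          fm <- movie_frame_matrix(st$frames)
          T <- min(30L, 60L - st$t0)
          rr <- vapply(cells, function(cl)
            transition_response(cell_response(cl, fm), st$t0, T),
            numeric(1))
          resp[[length(resp) + 1L]] <- rr
          lab <- c(lab, st$transition_type == "ground-to-sky")
        }
      }
    }
    rm <- do.call(cbind, resp)      # [neuron x event]
    for (n in seq_along(cells)) {
      out[[length(out) + 1L]] <- data.frame(
        velocity = v, neuron = n, family = cells[[n]]$family,
        auc = roc_auc(rm[n, ], lab)$auc)
    }
  }
  do.call(rbind, out)
}

#' Binned mean-response map over chromatic contrast
#'
#' Averages per-event responses in 10 x 10 bins of the (green, UV) contrast
#' plane within the given box; empty bins are `NA` (masked), not zero.
#'
#' @param events a [find_transitions()] table
#' @param responses per-event responses (same order as `events`)
#' @param bins bins per axis
#' @param box list with `xlim`, `ylim` covering the event contrasts
#' @return list of class `group_tuning_map`: `map` `[bins x bins]`
#'   (rows = green bins, cols = UV bins), `counts`, bin `breaks`
#' @export
group_tuning_map <- function(events, responses, bins = 10L, box = NULL) {
  if (is.null(box))
    box <- list(xlim = range(events$gamma_green),
                ylim = range(events$gamma_uv))
  bx <- seq(box$xlim[1], box$xlim[2], length.out = bins + 1L)
  by <- seq(box$ylim[1], box$ylim[2], length.out = bins + 1L)
  ix <- findInterval(events$gamma_green, bx, rightmost.closed = TRUE,
                     all.inside = TRUE)
  iy <- findInterval(events$gamma_uv, by, rightmost.closed = TRUE,
                     all.inside = TRUE)
  map <- matrix(NA_real_, bins, bins)
  counts <- matrix(0L, bins, bins)
  for (b in seq_along(ix)) {
    counts[ix[b], iy[b]] <- counts[ix[b], iy[b]] + 1L
    map[ix[b], iy[b]] <- if (is.na(map[ix[b], iy[b]])) responses[b]
      else map[ix[b], iy[b]] + responses[b]
  }
  map <- map / ifelse(counts == 0L, NA, counts)
  structure(list(map = map, counts = counts, breaks_green = bx,
                 breaks_uv = by),
            class = "group_tuning_map")
}
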