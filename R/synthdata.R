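## Synthetic data generation: dichromatic clip-structured movies, ground-truth
## model RGCs, and calcium-like recordings. Everything downstream of this file
## is testable against the ground truth these generators carry.

#' Default movie generator configuration
#'
#' The defaults mirror the recording conditions the pipeline emulates: 113
#' five-second clips (150 frames at 30 Hz) of which 5 form a fixed test
#' sequence presented three times; 15 of the 108 training clips are held out
#' for validation during model fitting; clip mean intensities lie in
#' \[0.04, 0.22\] on a \[0, 1\] intensity scale; "sky" clips have a higher UV
#' than green mean and "ground" clips the reverse, so ground-to-sky clip
#' transitions fall in the UV-positive/green-negative contrast quadrant.
#'
#' @param n_clips total number of distinct clips (train + test)
#' @param n_test number of test clips (fixed sequence, repeated)
#' @param n_validation number of training clips held out for validation
#' @param clip_len frames per clip
#' @param frame_rate stimulus frame rate in Hz
#' @param mean_range admissible range of per-clip, per-channel mean intensity
#' @param min_chromatic_sep minimum UV-green mean separation within a clip
#' @param texture_amp SD of the low-pass spatiotemporal texture (0 gives flat
#'   clips at their mean intensity)
#' @param texture_sigma_px,texture_sigma_t Gaussian smoothing scales of the
#'   texture in pixels / frames
#' @param sky_prob probability that a clip is labelled sky
#' @param n_test_presentations how many times the test sequence is presented
#' @param alternate_crops unused placeholder for upper/lower visual-field crop
#'   alternation; kept off (single virtual crop location)
#' @return a list of class `movie_config`
#' @export
movie_config <- function(n_clips = 113L, n_test = 5L, n_validation = 15L,
                         clip_len = 150L, frame_rate = 30,
                         mean_range = c(0.04, 0.22),
                         min_chromatic_sep = 0.02,
                         texture_amp = 0.08,
                         texture_sigma_px = 1.2, texture_sigma_t = 0.7,
                         sky_prob = 0.5, n_test_presentations = 3L,
                         alternate_crops = FALSE) {
  cfg <- list(n_clips = as.integer(n_clips), n_test = as.integer(n_test),
              n_validation = as.integer(n_validation),
              clip_len = as.integer(clip_len), frame_rate = frame_rate,
              mean_range = mean_range, min_chromatic_sep = min_chromatic_sep,
              texture_amp = texture_amp,
              texture_sigma_px = texture_sigma_px,
              texture_sigma_t = texture_sigma_t,
              sky_prob = sky_prob,
              n_test_presentations = as.integer(n_test_presentations),
              alternate_crops = alternate_crops)
  class(cfg) <- "movie_config"
  cfg
}

## Gaussian smoothing along the first dimension of a matrix (circular),
## used to low-pass the texture noise. stats::filter runs at C speed.
smooth_columns <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  g <- exp(-0.5 * ((-half:half) / sigma)^2)
  g <- g / sum(g)
  out <- stats::filter(m, g, method = "convolution", sides = 2,
                       circular = TRUE)
  matrix(as.numeric(out), nrow(m), ncol(m))
}

## One clip's texture: low-pass-filtered Gaussian noise, zero spatial mean in
## every frame (so full-field luminance equals the clip mean exactly and
## inter-clip transition contrasts are set by the clip means alone) and unit
## SD overall.
clip_texture <- function(clip_len, h, w, sigma_px, sigma_t) {
  x <- array(rnorm(clip_len * h * w), dim = c(clip_len, h, w))
  m <- matrix(x, clip_len, h * w)
  m <- smooth_columns(m, sigma_t)                       # time
  a <- array(m, dim = c(clip_len, h, w))
  a <- aperm(a, c(2, 1, 3))                             # h x t x w
  m <- smooth_columns(matrix(a, h, clip_len * w), sigma_px)
  a <- aperm(array(m, dim = c(h, clip_len, w)), c(3, 2, 1))  # w x t x h
  m <- smooth_columns(matrix(a, w, clip_len * h), sigma_px)
  a <- aperm(array(m, dim = c(w, clip_len, h)), c(2, 3, 1))  # t x h x w
  fm <- matrix(a, clip_len, h * w)
  a <- a - array(rowMeans(fm), dim = dim(a))   # zero mean per frame
  a / max(sd(a), 1e-12)
}

#' Generate a clip-structured dichromatic movie stimulus
#'
#' Builds a green/UV movie of `n_clips` clips with per-clip mean intensities
#' in the configured range and sky/ground chromatic statistics. The spatial
#' texture is low-pass-filtered Gaussian noise; it is centred per clip so each
#' clip's mean intensity is exact. Frames are laid out as the presentation
#' sequence with the fixed test block between two training half-sequences
#' (the test block is physically stored once; its repeated presentations are
#' bookkept via `n_test_presentations` and realised with independent noise at
#' recording time).
#'
#' @param config a [movie_config()]
#' @param seed integer seed; the generator is a pure function of
#'   (config, seed)
#' @return an object of class `movie_stimulus` with fields `frames`
#'   (array `[2, time, 18, 16]`, channels green then UV), `clip_ids` (per
#'   frame), `clip_labels`, `split` (train/validation/test per clip),
#'   `intensity_range` (per-channel min/max over training frames), and the
#'   generating config/seed
#' @export
generate_movie <- function(config = movie_config(), seed = 0L) {
  stopifnot(inherits(config, "movie_config"))
  if (config$n_clips - config$n_test < 1L || config$n_clips < 6L)
    stop("movie config must allow at least one training clip and a ",
         config$n_test, "-clip test set")
  set.seed(seed)
  nc <- config$n_clips
  h <- CANVAS_H; w <- CANVAS_W; cl <- config$clip_len

  ## clip labels: sky/ground, at least one of each
  labels <- ifelse(runif(nc) < config$sky_prob, "sky", "ground")
  if (all(labels == "sky")) labels[1] <- "ground"
  if (all(labels == "ground")) labels[1] <- "sky"

  ## per-clip channel means: the UV-dominant and green-dominant channels
  ## draw from disjoint bands of the intensity range (split at its middle,
  ## separated by min_chromatic_sep), so every ground-to-sky transition
  ## increases UV and decreases green regardless of which clips adjoin
  mid <- mean(config$mean_range)
  gap <- config$min_chromatic_sep / 2
  bw <- 0.05   # band width: keeps inter-clip luminance steps moderate
  lo_band <- function(n) runif(n, max(config$mean_range[1], mid - gap - bw),
                               mid - gap)
  hi_band <- function(n) runif(n, mid + gap,
                               min(config$mean_range[2], mid + gap + bw))
  g_lo <- lo_band(nc); u_lo <- lo_band(nc)
  g_hi <- hi_band(nc); u_hi <- hi_band(nc)
  mean_green <- ifelse(labels == "sky", g_lo, g_hi)
  mean_uv <- ifelse(labels == "sky", u_hi, u_lo)

  ## splits and presentation order
  test_ids <- sort(sample.int(nc, config$n_test))
  train_ids <- setdiff(seq_len(nc), test_ids)
  val_ids <- sort(sample(train_ids, min(config$n_validation,
                                        max(0L, length(train_ids) - 1L))))
  split <- rep("train", nc)
  split[val_ids] <- "validation"
  split[test_ids] <- "test"
  train_order <- sample(train_ids)
  half <- ceiling(length(train_order) / 2)
  clip_order <- c(train_order[seq_len(half)], test_ids,
                  train_order[-seq_len(half)])

  frames <- array(0, dim = c(N_CHAN, nc * cl, h, w))
  clip_ids <- integer(nc * cl)
  for (k in seq_along(clip_order)) {
    id <- clip_order[k]
    idx <- ((k - 1L) * cl + 1L):(k * cl)
    clip_ids[idx] <- id
    means <- c(mean_green[id], mean_uv[id])
    for (ch in 1:2) {
      if (config$texture_amp > 0) {
        tex <- clip_texture(cl, h, w, config$texture_sigma_px,
                            config$texture_sigma_t)
        ## scale the texture so intensities rarely leave [0, 1] (2.5 SD
        ## headroom; dim clips get proportionally weaker texture, like
        ## low-light scenes), clipping the rare excursions -- full-field
        ## luminance then equals the clip mean up to a negligible clipped
        ## mass, far below the sky/ground band separation
        amp <- min(config$texture_amp,
                   0.95 * means[ch] / 2.5,
                   0.95 * (1 - means[ch]) / 2.5)
        frames[ch, idx, , ] <- pmin(pmax(means[ch] + amp * tex, 0), 1)
      } else {
        frames[ch, idx, , ] <- means[ch]
      }
    }
  }

  train_frames <- clip_ids %in% setdiff(seq_len(nc), test_ids)
  intensity_range <- rbind(
    green = range(frames[1, train_frames, , ]),
    uv = range(frames[2, train_frames, , ]))
  colnames(intensity_range) <- c("min", "max")

  out <- list(frames = frames, frame_rate = config$frame_rate,
              clip_len = cl, clip_ids = clip_ids,
              clip_labels = setNames(labels, seq_len(nc)),
              clip_means = cbind(green = mean_green, uv = mean_uv),
              split = setNames(split, seq_len(nc)),
              test_clip_ids = test_ids,
              n_test_presentations = config$n_test_presentations,
              intensity_range = intensity_range,
              config = config, seed = seed)
  class(out) <- "movie_stimulus"
  out
}

#' Frame indices of the test block of a movie
#' @param movie a `movie_stimulus`
#' @return integer vector of frame indices covering the fixed test sequence
#' @export
test_frame_indices <- function(movie) {
  which(movie$clip_ids %in% movie$test_clip_ids)
}

#' Default population generator configuration
#'
#' Families: fast `ON`, `OFF`, `ON-OFF`, `slow-ON`, and the nonlinearly
#' colour-opponent `opponent-SbC` (UV-ON/green-OFF, suppressed by green
#' contrast increments). Receptive-field centres are kept inside the region
#' seen by the model core after valid convolution.
#'
#' @param families named integer vector of per-family cell counts
#' @param rf_sigma_range range of spatial-filter SDs in pixels
#' @param rf_margin margin (pixels) keeping RF centres away from the border
#' @param drive_gain fixed gain mapping filtered stimulus drive to
#'   nonlinearity input units (chosen so typical movie drives have SD near 1)
#' @param noise_level SD of additive white trace noise
#' @param baseline baseline firing rate added to all cells
#' @return list of class `population_config`
#' @export
population_config <- function(families = c(`ON` = 6L, `OFF` = 6L,
                                           `ON-OFF` = 6L, `slow-ON` = 6L,
                                           `opponent-SbC` = 6L),
                              rf_sigma_range = c(1.6, 2.4),
                              rf_margin = 6, drive_gain = 8,
                              assumed_drive_sd = 2.3,
                              rate_max = 150,
                              noise_level = 1.0, baseline = 0.2) {
  if (length(families) == 0 || sum(families) == 0)
    stop("population config needs a non-empty family list")
  known <- c("ON", "OFF", "ON-OFF", "slow-ON", "opponent-SbC")
  if (!all(names(families) %in% known))
    stop("unknown family: ", setdiff(names(families), known))
  cfg <- list(families = families, rf_sigma_range = rf_sigma_range,
              rf_margin = rf_margin, drive_gain = drive_gain,
              assumed_drive_sd = assumed_drive_sd, rate_max = rate_max,
              noise_level = noise_level, baseline = baseline)
  class(cfg) <- "population_config"
  cfg
}

## Biphasic temporal filter on a 21-tap causal grid (tap 1 = current frame),
## zero mean (no DC response) and unit L2 norm.
biphasic_kernel <- function(tau_rise, tau_decay, rebound, len = 21L,
                            frame_rate = FRAME_RATE) {
  t <- (0:(len - 1L)) / frame_rate
  k <- (t / tau_rise) * exp(-t / tau_rise) -
    rebound * (t / tau_decay) * exp(-t / tau_decay)
  k <- k - mean(k)
  k / l2norm(k)
}

gaussian_blob <- function(mu_x, mu_y, sigma, h = CANVAS_H, w = CANVAS_W) {
  g <- outer(seq_len(h), seq_len(w), function(y, x)
    exp(-((y - mu_y)^2 + (x - mu_x)^2) / (2 * sigma^2)))
  g / l2norm(g)
}

#' Generate a ground-truth simulated RGC population
#'
#' Each cell is a linear-nonlinear unit: per-channel unit-norm Gaussian
#' spatial filters at a common receptive-field location, per-channel zero-mean
#' unit-norm biphasic temporal filters, signed chromatic weights, and a
#' family-specific rectifying output stage. `opponent-SbC` cells carry a
#' rectified suppression of green contrast increments plus a thresholded
#' excitation by strong green decrements and a small positive linear green
#' term, so their UV-ON/green-OFF opponency only appears at high contrast and
#' is invisible to a purely linear fit at low contrast.
#'
#' @param config a [population_config()]
#' @param seed integer seed
#' @return list of `simulated_cell` objects
#' @export
generate_population <- function(config = population_config(), seed = 1L) {
  stopifnot(inherits(config, "population_config"))
  set.seed(seed)
  cells <- list()
  id <- 0L
  for (fam in names(config$families)) {
    for (i in seq_len(config$families[[fam]])) {
      id <- id + 1L
      ## keep centres strictly inside the 8 x 6 region the model core sees
      ## after valid convolution (input pixels 6..11 x, 6..13 y)
      m <- config$rf_margin
      mu_x <- runif(1, m + 0.5, CANVAS_W - m + 0.5)
      mu_y <- runif(1, m + 0.5, CANVAS_H - m + 0.5)
      sigma <- runif(1, config$rf_sigma_range[1], config$rf_sigma_range[2])
      sp <- gaussian_blob(mu_x, mu_y, sigma)
      ## suppressed-by-contrast cells are slow/sustained, like slow ON cells
      kin <- switch(fam,
        "slow-ON" = list(rise = 0.11, decay = 0.18, rebound = 0.25),
        "opponent-SbC" = list(rise = 0.11, decay = 0.18, rebound = 0.25),
        list(rise = 0.035, decay = 0.08, rebound = 0.9))
      tk <- biphasic_kernel(kin$rise, kin$decay, kin$rebound)
      wmag_g <- runif(1, 0.7, 1.0)
      wmag_u <- runif(1, 0.7, 1.0)
      cw <- switch(fam,
        "OFF" = c(green = -wmag_g, uv = -wmag_u),
        "opponent-SbC" = c(green = -runif(1, 2.0, 2.8),
                           uv = runif(1, 0.9, 1.2)),
        c(green = wmag_g, uv = wmag_u))
      nl <- switch(fam,
        "ON" = list(type = "relu", theta = runif(1, 0.3, 0.7),
                    gain = runif(1, 2, 4)),
        "slow-ON" = list(type = "relu", theta = runif(1, 0.2, 0.5),
                         gain = runif(1, 2, 4)),
        "OFF" = list(type = "relu", theta = runif(1, 0.3, 0.7),
                     gain = runif(1, 2, 4)),
        "ON-OFF" = list(type = "abs", theta = runif(1, 0.4, 0.8),
                        gain = runif(1, 2, 4)),
        ## green thresholds sit at about two SDs of the movie-driven green
        ## drive (SD near 3 in gain units): the rectified suppression and
        ## green-OFF excitation engage only at high contrast, and the weak
        ## linear green-ON term cancels their small average slope -- the
        ## cell's time-averaged linear green sensitivity is near zero while
        ## its high-contrast sensitivity is strongly green-OFF
        "opponent-SbC" = {
          kap <- abs(cw[["green"]])
          th_g <- runif(1, 4.2, 4.8); th_s <- runif(1, 3, 3.7)
          k_off <- runif(1, 2.8, 3.2) * kap
          ## linear green-ON term sized to cancel the regression slope of
          ## the two rectified green legs under the movie-calibrated drive
          ## scale (drive SD about 2.3 in gain units): the cell's
          ## time-averaged linear green sensitivity is near zero while its
          ## high-contrast sensitivity is strongly green-OFF
          sdg <- config$assumed_drive_sd
          leg <- function(th) stats::integrate(function(x)
            x * (x - th) * dnorm(x, 0, sdg), th, Inf)$value / sdg^2
          list(type = "sbc", theta = runif(1, 0.15, 0.35),
               gain = runif(1, 2, 4),
               theta_g = th_g, theta_s = th_s, kappa_off = k_off,
               w_lin_g = kap * leg(th_s) + k_off * leg(th_g))
        })
      cell <- list(cell_id = id, family = fam,
                   spatial_filter = list(green = sp, uv = sp),
                   temporal_filter = list(green = tk, uv = tk),
                   chromatic_weights = cw,
                   output_nonlinearity = nl,
                   rf_location = c(x = mu_x, y = mu_y),
                   noise_level = config$noise_level,
                   baseline = config$baseline,
                   rate_max = config$rate_max,
                   drive_gain = config$drive_gain)
      class(cell) <- "simulated_cell"
      cells[[id]] <- cell
    }
  }
  cells
}

## Per-channel drive of one cell to a frame stack [576 x T] (green pixels
## 1:288, UV 289:576, frames column-major 18 x 16), causal zero-padded
## temporal convolution.
cell_drives <- function(cell, frames_mat) {
  np <- CANVAS_H * CANVAS_W
  drv <- function(sp, tk, rows) {
    s <- as.numeric(crossprod(as.numeric(sp), frames_mat[rows, , drop = FALSE]))
    L <- length(tk)
    sp_pad <- c(rep(0, L - 1), s)
    as.numeric(stats::filter(sp_pad, tk, method = "convolution",
                             sides = 1))[L:(L + length(s) - 1L)]
  }
  list(green = drv(cell$spatial_filter$green, cell$temporal_filter$green,
                   seq_len(np)),
       uv = drv(cell$spatial_filter$uv, cell$temporal_filter$uv,
                np + seq_len(np)))
}

## Ground-truth firing rate of a cell given its per-channel drives
## (already in filter output units; gain is applied here).
cell_rate_from_drives <- function(cell, dg, du) {
  g <- cell$drive_gain
  cw <- cell$chromatic_weights
  nl <- cell$output_nonlinearity
  r <- switch(nl$type,
    relu = nl$gain * relu(g * (cw["green"] * dg + cw["uv"] * du) - nl$theta),
    abs = {
      d <- g * (cw["green"] * dg + cw["uv"] * du)
      nl$gain * (relu(d - nl$theta) + relu(-d - nl$theta))
    },
    sbc = {
      dgu <- g * dg; duu <- g * du
      kap <- abs(cw["green"])
      ## both green-contrast terms are thresholded, so at low contrast only
      ## the weak linear green-ON term is visible to a linear fit; at high
      ## contrast green increments suppress and green decrements excite
      pre <- cw["uv"] * duu +
        nl$w_lin_g * dgu -
        kap * relu(dgu - nl$theta_s) +
        nl$kappa_off * relu(-dgu - nl$theta_g)
      nl$gain * relu(pre - nl$theta)
    },
    stop("unknown nonlinearity type ", nl$type))
  ## soft physiological ceiling: firing rates saturate smoothly
  rmax <- if (is.null(cell$rate_max)) Inf else cell$rate_max
  if (is.finite(rmax)) r <- rmax * (1 - exp(-r / rmax))
  as.numeric(r) + cell$baseline
}

#' Ground-truth response of a simulated cell to a movie
#' @param cell a `simulated_cell`
#' @param frames_mat frame stack `[576 x T]` (see [movie_frame_matrix()])
#' @return firing-rate vector at the movie frame rate
#' @export
cell_response <- function(cell, frames_mat) {
  d <- cell_drives(cell, frames_mat)
  cell_rate_from_drives(cell, d$green, d$uv)
}

#' Flatten a movie's frames to a `[576 x T]` matrix
#'
#' Rows 1:288 are green pixels (column-major 18 x 16), rows 289:576 UV.
#' @param movie a `movie_stimulus`, or an array `[2, T, 18, 16]`
#' @return numeric matrix `[576 x T]`
#' @export
movie_frame_matrix <- function(movie) {
  fr <- if (inherits(movie, "movie_stimulus")) movie$frames else movie
  d <- dim(fr)
  t(matrix(aperm(fr, c(2, 3, 4, 1)), d[2], d[3] * d[4] * d[1]))
}

#' Probe a cell with a full-field chromatic step
#'
#' Presents a uniform grey screen that steps to grey + (green_dir, uv_dir) *
#' amplitude at frame 31 and returns the cell's peak rate after the step.
#' Used to assert chromatic preferences of the generator's response functions.
#'
#' @param cell a `simulated_cell`
#' @param green_dir,uv_dir step direction per channel (+1, 0, -1)
#' @param amplitude step size in intensity units
#' @param grey background intensity
#' @return peak firing rate in the second after the step
#' @export
probe_fullfield_step <- function(cell, green_dir, uv_dir, amplitude = 0.12,
                                 grey = 0.13) {
  T <- 90L
  fr <- array(grey, dim = c(2, T, CANVAS_H, CANVAS_W))
  fr[1, 31:T, , ] <- grey + green_dir * amplitude
  fr[2, 31:T, , ] <- grey + uv_dir * amplitude
  r <- cell_response(cell, movie_frame_matrix(fr))
  max(r[31:60])
}

#' Simulate a calcium-imaging recording of a population
#'
#' Applies each cell's ground-truth response function to the movie (30 Hz
#' rates), convolves with a calcium kernel, samples at the imaging rate
#' (7.8125 Hz), and adds slow sinusoidal drift plus white noise. A
#' pre-stimulus baseline segment is prepended to the traces (for SD
#' normalisation during detrending). The fixed test sequence is rendered as
#' `n_test_presentations` independent-noise repeats from the identical
#' stimulus.
#'
#' @param cells list of `simulated_cell`
#' @param movie a `movie_stimulus`
#' @param seed integer seed
#' @param calcium one of "exponential" (default, decay `calcium_tau` s) or
#'   "identity" (traces are the sampled rates; for pipeline tests)
#' @param calcium_tau calcium decay time constant in seconds
#' @param drift_amp amplitude of the slow additive drift (0 disables)
#' @param noise_level overrides the cells' trace noise SD if not `NULL`
#' @param pre_stim_s seconds of pre-stimulus baseline prepended to traces
#' @param trace_rate imaging sampling rate in Hz
#' @return an object of class `response_pack` with fields `traces`
#'   `[neuron x time]`, `rates` `[neuron x time]` (ground truth at 30 Hz),
#'   `test_repeats` `[neuron x repeat x time]`, `t0` (stimulus-start index in
#'   the traces), and provenance
#' @export
simulate_recording <- function(cells, movie, seed = 0L,
                               calcium = c("exponential", "identity"),
                               calcium_tau = 1.0, drift_amp = 1.0,
                               noise_level = NULL, pre_stim_s = 10,
                               trace_rate = TRACE_RATE) {
  calcium <- match.arg(calcium)
  stopifnot(inherits(movie, "movie_stimulus"))
  if (trace_rate <= 0 || movie$frame_rate <= 0)
    stop("sampling-rate mismatch: rates must be positive")
  set.seed(seed)
  fm <- movie_frame_matrix(movie)
  Tm <- ncol(fm)
  N <- length(cells)
  rates <- matrix(0, N, Tm)
  for (n in seq_len(N)) rates[n, ] <- cell_response(cells[[n]], fm)

  fr <- movie$frame_rate
  ca_kernel <- if (calcium == "identity") 1 else {
    L <- ceiling(5 * calcium_tau * fr)
    k <- exp(-(0:(L - 1L)) / (calcium_tau * fr))
    k / sum(k)
  }
  ca_conv <- function(r) {
    L <- length(ca_kernel)
    if (L == 1L) return(r)
    pad <- c(rep(0, L - 1L), r)
    as.numeric(stats::filter(pad, ca_kernel, method = "convolution",
                             sides = 1))[L:(L + length(r) - 1L)]
  }
  sample_trace <- function(x) {
    tt <- seq(0, (length(x) - 1L) / fr, by = 1 / trace_rate)
    tt <- tt[tt <= (length(x) - 1L) / fr]
    stats::approx(x = (seq_along(x) - 1L) / fr, y = x, xout = tt)$y
  }

  n_pre <- round(pre_stim_s * trace_rate)
  t0 <- n_pre + 1L
  one_trace <- function(cell, r) {
    s <- sample_trace(ca_conv(r))
    full <- c(rep(0, n_pre), s)
    nl <- if (is.null(noise_level)) cell$noise_level else noise_level
    if (drift_amp > 0) {
      tt <- seq_along(full) / trace_rate
      f <- runif(1, 0.005, 0.02); ph <- runif(1, 0, 2 * pi)
      full <- full + drift_amp * sin(2 * pi * f * tt + ph)
    }
    if (nl > 0) full <- full + rnorm(length(full), 0, nl)
    full
  }

  traces <- t(vapply(seq_len(N), function(n) one_trace(cells[[n]], rates[n, ]),
                     numeric(n_pre + length(sample_trace(rates[1, ])))))

  ## test repeats: identical stimulus, independent noise (no drift, no
  ## pre-stimulus padding; repeats are already aligned)
  ti <- test_frame_indices(movie)
  nrep <- movie$n_test_presentations
  Ttr <- length(sample_trace(rates[1, ti]))
  test_repeats <- array(0, dim = c(N, nrep, Ttr))
  for (n in seq_len(N)) {
    base <- sample_trace(ca_conv(rates[n, ti]))
    nl <- if (is.null(noise_level)) cells[[n]]$noise_level else noise_level
    for (i in seq_len(nrep))
      test_repeats[n, i, ] <- base +
        if (nl > 0) rnorm(Ttr, 0, nl) else 0
  }

  out <- list(traces = traces, rates = rates, test_repeats = test_repeats,
              t0 = t0, trace_rate = trace_rate, frame_rate = fr,
              test_frames = ti, recording_id = rep(1L, N),
              ground_truth = cells, calcium = calcium,
              calcium_tau = calcium_tau, seed = seed)
  class(out) <- "response_pack"
  out
}
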