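## Training: Poisson regression with Adam, early stopping on validation
## correlation with restore-and-decay cycles, and seed-indexed ensembles.

#' Training schedule configuration
#'
#' Defaults follow the reference schedule: Adam with initial learning rate
#' 0.01, batch size 32, chunk size 50 frames, early stopping with patience 5
#' on validation correlation, and 4 restore-and-decay cycles with learning
#' rate decay 0.3.
#'
#' @param lr initial learning rate
#' @param lr_decay decay factor applied at each early-stopping cycle
#' @param n_cycles number of restore-and-decay cycles
#' @param patience epochs without validation improvement per cycle
#' @param batch_size chunks per gradient step
#' @param chunk_size frames per chunk
#' @param chunk_stride stride between chunk starts (defaults to chunk_size)
#' @param max_epochs hard cap on total epochs
#' @param n_members ensemble size (models with distinct init seeds)
#' @param grad_clip global gradient-norm ceiling per step (the gradient is
#'   rescaled if its joint L2 norm exceeds this; guards Poisson-loss spikes
#'   from rare high-rate events)
#' @param readout_lr_mult learning-rate multiplier for the readout location
#'   and size parameters (`mu`, `sigma`); with Adam, `mu` moves at most
#'   `lr * mult` pixels per step, so at CPU-scale step counts a multiplier
#'   above 1 lets receptive-field locations travel across the canvas
#' @return list of class `train_schedule`
#' @export
train_schedule <- function(lr = 0.01, lr_decay = 0.3, n_cycles = 4L,
                           patience = 5L, batch_size = 32L, chunk_size = 50L,
                           chunk_stride = NULL, max_epochs = 200L,
                           n_members = 5L, readout_lr_mult = 10,
                           grad_clip = 500) {
  s <- list(lr = lr, lr_decay = lr_decay, n_cycles = as.integer(n_cycles),
            patience = as.integer(patience),
            batch_size = as.integer(batch_size),
            chunk_size = as.integer(chunk_size),
            chunk_stride = as.integer(if (is.null(chunk_stride)) chunk_size
                                      else chunk_stride),
            max_epochs = as.integer(max_epochs),
            n_members = as.integer(n_members),
            readout_lr_mult = readout_lr_mult,
            grad_clip = grad_clip)
  class(s) <- "train_schedule"
  s
}

## Per-channel z-scoring constants from the training frames of a movie.
movie_norm_stats <- function(movie) {
  fm <- movie_frame_matrix(movie)
  train_cols <- movie$clip_ids %in%
    names(movie$split)[movie$split != "test"]
  np <- CANVAS_H * CANVAS_W
  g <- fm[seq_len(np), train_cols]; u <- fm[np + seq_len(np), train_cols]
  m <- c(green = mean(g), uv = mean(u))
  s <- c(green = sd(g), uv = sd(u))
  zr <- rbind(green = (movie$intensity_range["green", ] - m[1]) / s[1],
              uv = (movie$intensity_range["uv", ] - m[2]) / s[2])
  list(mean = m, sd = s, zrange = zr)
}

## z-score a [576 x T] frame matrix with stored constants.
zscore_frames <- function(fm, norm) {
  np <- CANVAS_H * CANVAS_W
  fm[seq_len(np), ] <- (fm[seq_len(np), ] - norm$mean[1]) / norm$sd[1]
  fm[np + seq_len(np), ] <- (fm[np + seq_len(np), ] - norm$mean[2]) / norm$sd[2]
  fm
}

## Contiguous runs of frames belonging to a split ("train" or "validation").
split_runs <- function(movie, which_split) {
  in_split <- movie$split[as.character(movie$clip_ids)] == which_split
  r <- rle(as.logical(in_split))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

## Valid chunk start frames given runs and a chunk length.
chunk_starts <- function(runs, chunk, stride) {
  unlist(lapply(seq_len(nrow(runs)), function(i) {
    s <- runs[i, "start"]; e <- runs[i, "end"]
    if (e - s + 1L < chunk) return(integer(0))
    seq(s, e - chunk + 1L, by = stride)
  }))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, skip = character(0),
                      lr_mult = c(mu = 1, sig = 1)) {
  st$t <- st$t + 1
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (k in names(params)) {
    if (k %in% skip || is.null(grads[[k]])) next
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * grads[[k]]
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * grads[[k]]^2
    lk <- lr * if (k %in% names(lr_mult)) lr_mult[[k]] else 1
    params[[k]] <- params[[k]] -
      lk * (st$m[[k]] / bc1) / (sqrt(st$v[[k]] / bc2) + eps)
  }
  list(params = params, st = st)
}

## Keep readout parameters inside their feasible set.
project_params <- function(p, a) {
  p$sig <- pmax(p$sig, 1.0)
  p$mu["x", ] <- pmin(pmax(p$mu["x", ], 1), a$W)
  p$mu["y", ] <- pmin(pmax(p$mu["y", ], 1), a$H)
  p$tau <- max(p$tau, 0.05)
  p
}

## Mean validation correlation across neurons.
validation_corr <- function(model, frames_z, rates) {
  sup <- model$arch$L1 + model$arch$L2 - 2L
  pred <- predict_rates(model, frames_z)
  target <- rates[, (sup + 1L):ncol(rates), drop = FALSE]
  mean(vapply(seq_len(nrow(pred)), function(n)
    as.numeric(safe_cor(pred[n, ], target[n, ])), numeric(1)))
}

#' Train a single digital-twin model
#'
#' Minimises the Poisson loss with Adam over 50-frame chunks of the training
#' clips, early-stops on the mean validation correlation (patience epochs),
#' and runs restore-and-decay cycles (restore best weights, multiply the
#' learning rate by the decay factor). Deterministic given `seed`.
#'
#' @param movie a `movie_stimulus`
#' @param rates matrix `[neuron x frames]` of firing rates at 30 Hz aligned
#'   with the movie frames
#' @param arch a [twin_arch()]
#' @param schedule a [train_schedule()]
#' @param seed init/shuffling seed for this member
#' @param verbose print per-epoch progress
#' @return trained `twin_model` with a `log` data.frame of the schedule
#' @export
train_twin <- function(movie, rates, arch = twin_arch(),
                       schedule = train_schedule(), seed = 0L,
                       verbose = FALSE) {
  stopifnot(inherits(movie, "movie_stimulus"),
            ncol(rates) == length(movie$clip_ids))
  if (!any(movie$split == "validation"))
    stop("movie has no validation clips")
  norm <- movie_norm_stats(movie)
  fm_z <- zscore_frames(movie_frame_matrix(movie), norm)

  tr_runs <- split_runs(movie, "train")
  starts <- chunk_starts(tr_runs, schedule$chunk_size, schedule$chunk_stride)
  if (length(starts) < schedule$batch_size)
    stop("not enough training chunks for one batch")
  val_runs <- split_runs(movie, "validation")
  val_cols <- unlist(lapply(seq_len(nrow(val_runs)), function(i)
    val_runs[i, "start"]:val_runs[i, "end"]))
  ## validation clips are contiguous by construction of the clip order; if
  ## not, use the longest run
  if (nrow(val_runs) > 1) {
    lens <- val_runs[, "end"] - val_runs[, "start"] + 1L
    i <- which.max(lens)
    val_cols <- val_runs[i, "start"]:val_runs[i, "end"]
  }
  val_fz <- fm_z[, val_cols, drop = FALSE]
  val_rates <- rates[, val_cols, drop = FALSE]

  model <- init_model(nrow(rates), arch, seed = seed,
                      mean_rate = max(mean(rates), 0.05))
  model$norm <- norm
  sup <- arch$L1 + arch$L2 - 2L
  D <- CANVAS_H * CANVAS_W * N_CHAN
  ad <- adam_init(model$params)
  skip <- if (arch$train_tau) character(0) else "tau"
  lr <- schedule$lr
  best <- list(corr = -Inf, params = model$params, state = model$state)
  cycle <- 1L; bad <- 0L
  log <- data.frame()
  epoch <- 0L
  set.seed(seed + 10000L)
  while (epoch < schedule$max_epochs) {
    epoch <- epoch + 1L
    ord <- sample(starts)
    nb <- length(ord) %/% schedule$batch_size
    ep_loss <- 0
    for (ib in seq_len(nb)) {
      bs <- ord[((ib - 1L) * schedule$batch_size + 1L):
                  (ib * schedule$batch_size)]
      To <- schedule$chunk_size - sup
      xb <- array(0, dim = c(D, schedule$chunk_size, length(bs)))
      tba <- array(0, dim = c(nrow(rates), length(bs), To))
      for (j in seq_along(bs)) {
        cols <- bs[j]:(bs[j] + schedule$chunk_size - 1L)
        xb[, , j] <- fm_z[, cols]
        tba[, j, ] <- rates[, cols[(sup + 1L):length(cols)]]
      }
      tb <- matrix(tba, nrow(rates), length(bs) * To)
      fw <- twin_forward(model, xb, training = TRUE, cache = TRUE)
      loss <- poisson_loss(fw$y, tb) / length(bs)
      gy <- poisson_loss_grad(fw$y, tb) / length(bs)
      gr <- twin_backward(model, fw, gy)
      if (is.finite(schedule$grad_clip)) {
        gn <- sqrt(sum(vapply(gr, function(g) sum(g^2), numeric(1))))
        if (gn > schedule$grad_clip)
          gr <- lapply(gr, function(g) g * (schedule$grad_clip / gn))
      }
      up <- adam_step(model$params, gr, ad, lr, skip = skip,
                      lr_mult = c(mu = schedule$readout_lr_mult,
                                  sig = schedule$readout_lr_mult))
      model$params <- project_params(up$params, arch)
      ad <- up$st
      model$state <- fw$new_state
      ep_loss <- ep_loss + loss
    }
    vc <- validation_corr(model, val_fz, val_rates)
    improved <- vc > best$corr + 1e-6
    if (improved) {
      best <- list(corr = vc, params = model$params, state = model$state)
      bad <- 0L
    } else bad <- bad + 1L
    log <- rbind(log, data.frame(epoch = epoch, cycle = cycle, lr = lr,
                                 loss = ep_loss / nb, val_corr = vc,
                                 improved = improved))
    if (verbose)
      message(sprintf("epoch %d cycle %d lr %.4g loss %.4f val %.4f",
                      epoch, cycle, lr, ep_loss / nb, vc))
    if (bad >= schedule$patience) {
      model$params <- best$params
      model$state <- best$state
      cycle <- cycle + 1L
      bad <- 0L
      if (cycle > schedule$n_cycles) break
      lr <- lr * schedule$lr_decay
    }
  }
  model$params <- best$params
  model$state <- best$state
  model$trained <- TRUE
  model$log <- log
  model$val_corr <- best$corr
  model
}

#' Train an ensemble of digital-twin models
#'
#' Trains `schedule$n_members` instances of the same model initialised with
#' distinct seeds (`seed + member - 1`); the ensemble prediction is the
#' arithmetic mean of the member outputs.
#'
#' @inheritParams train_twin
#' @return object of class `twin_ensemble`
#' @export
train_ensemble <- function(movie, rates, arch = twin_arch(),
                           schedule = train_schedule(), seed = 0L,
                           verbose = FALSE) {
  members <- lapply(seq_len(schedule$n_members), function(i)
    train_twin(movie, rates, arch, schedule, seed = seed + i - 1L,
               verbose = verbose))
  ens <- list(members = members,
              seeds = seed + seq_len(schedule$n_members) - 1L,
              arch = arch, n_neurons = members[[1]]$n_neurons,
              norm = members[[1]]$norm)
  class(ens) <- "twin_ensemble"
  ens
}

#' Evaluate a model on repeated test responses
#'
#' Computes, per neuron, the correlation to the mean (prediction vs
#' repeat-averaged response) and the mean single-trial correlation
#' (average of per-repeat correlations). Constant predictions are flagged
#' and scored 0.
#'
#' @param model `twin_model` or `twin_ensemble`
#' @param movie a `movie_stimulus` (its test block is used)
#' @param repeats array `[neuron x repeat x time]` of responses at 30 Hz
#'   aligned with the test-block frames
#' @return data.frame with `corr_to_mean`, `mean_single_trial_corr`, and a
#'   `degenerate` flag per neuron
#' @export
evaluate_model <- function(model, movie, repeats) {
  stopifnot(dim(repeats)[2] >= 2)
  norm <- if (inherits(model, "twin_ensemble")) model$norm else model$norm
  arch <- model$arch
  ti <- test_frame_indices(movie)
  fz <- zscore_frames(movie_frame_matrix(movie), norm)[, ti, drop = FALSE]
  sup <- arch$L1 + arch$L2 - 2L
  pred <- predict_rates(model, fz)
  N <- dim(repeats)[1]
  keep <- (sup + 1L):dim(repeats)[3]
  out <- data.frame(neuron = seq_len(N), corr_to_mean = 0,
                    mean_single_trial_corr = 0, degenerate = FALSE)
  for (n in seq_len(N)) {
    avg <- colMeans(repeats[n, , keep])
    c2m <- safe_cor(pred[n, ], avg)
    sts <- vapply(seq_len(dim(repeats)[2]), function(i)
      as.numeric(safe_cor(pred[n, ], repeats[n, i, keep])), numeric(1))
    out$corr_to_mean[n] <- as.numeric(c2m)
    out$mean_single_trial_corr[n] <- mean(sts)
    out$degenerate[n] <- isTRUE(attr(c2m, "degenerate"))
  }
  out
}

#' Ensemble prediction as mean of member outputs
#' @param ensemble a `twin_ensemble`
#' @param x stimulus array `[576 x T x B]` (z-scored)
#' @param readout optional readout override (list with `mu`, `sig`)
#' @return matrix `[N x (T-30)*B]`
#' @export
ensemble_forward <- function(ensemble, x, readout = NULL) {
  outs <- lapply(ensemble$members, function(m)
    twin_forward(m, x, training = FALSE, readout = readout)$y)
  Reduce(`+`, outs) / length(outs)
}
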