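## Minimal hand-built movie: flat clips with known means and labels.
flat_movie <- function(means_green, means_uv, labels) {
  nc <- length(labels); cl <- 60L
  frames <- array(0, dim = c(2, nc * cl, CANVAS_H, CANVAS_W))
  ids <- rep(seq_len(nc), each = cl)
  for (k in seq_len(nc)) {
    frames[1, ids == k, , ] <- means_green[k]
    frames[2, ids == k, , ] <- means_uv[k]
  }
  structure(list(frames = frames, frame_rate = 30, clip_len = cl,
                 clip_ids = ids,
                 clip_labels = setNames(labels, seq_len(nc)),
                 split = setNames(rep("train", nc), seq_len(nc)),
                 test_clip_ids = integer(0), n_test_presentations = 3L,
                 intensity_range = rbind(green = c(min = 0, max = 1),
                                         uv = c(min = 0, max = 1)),
                 config = movie_config(), seed = 0L),
            class = "movie_stimulus")
}

test_that("transition events carry exact contrasts of flat clips", {
  mv <- flat_movie(means_green = c(0.20, 0.06, 0.20, 0.20),
                   means_uv = c(0.06, 0.20, 0.06, 0.06),
                   labels = c("ground", "sky", "ground", "ground"))
  ev <- find_transitions(mv)
  expect_equal(nrow(ev), 3)                 # one event per clip boundary
  expect_equal(ev$type, c("ground-to-sky", "sky-to-ground",
                          "ground-to-ground"))
  expect_equal(ev$gamma_green, c(-0.14, 0.14, 0), tolerance = 1e-12)
  expect_equal(ev$gamma_uv, c(0.14, -0.14, 0), tolerance = 1e-12)
  ## identical adjacent clips: zero contrast
  expect_equal(ev$gamma_green[3], 0)
  ## ground-to-sky sits in the UV-positive / green-negative quadrant
  g2s <- ev[ev$type == "ground-to-sky", ]
  expect_true(all(g2s$gamma_uv > 0 & g2s$gamma_green < 0))
})

test_that("generated movies put ground-to-sky transitions in the opponent quadrant", {
  mv <- generate_movie(movie_config(n_clips = 20, n_validation = 2), seed = 4)
  ev <- find_transitions(mv)
  g2s <- ev[ev$type == "ground-to-sky", ]
  expect_gt(nrow(g2s), 0)
  expect_true(all(g2s$gamma_uv > 0 & g2s$gamma_green < 0))
})

test_that("transition response is the baseline-subtracted window mean", {
  expect_equal(transition_response(rep(5, 100), 10), 0)
  r <- c(rep(1, 10), rep(3, 40))
  expect_equal(transition_response(r, 10), 2)
  ## linear ramp vs an explicit 30-term sum oracle
  r2 <- pmax(seq_len(60) - 20, 0)
  oracle <- sum(sapply(1:30, function(k) r2[20 + k])) / 30 - r2[20]
  expect_equal(transition_response(r2, 20), oracle)
  expect_error(transition_response(rep(1, 20), 10), "window")
})

test_that("ROC/AUC: separation, chance level, Mann-Whitney agreement", {
  roc <- roc_auc(c(rep(0, 50), rep(1, 50)), c(rep(FALSE, 50), rep(TRUE, 50)))
  expect_equal(roc$auc, 1)
  expect_length(roc$thresholds, 40)
  set.seed(5)
  r <- rnorm(4000); l <- sample(c(TRUE, FALSE), 4000, replace = TRUE)
  expect_equal(roc_auc(r, l)$auc, 0.5, tolerance = 0.05)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "class")

  ## pairwise-probability oracle over 200 random instances
  set.seed(6)
  maxdiff <- 0
  for (i in 1:200) {
    n1 <- sample(20:60, 1); n0 <- sample(20:60, 1)
    resp <- c(rnorm(n1, runif(1, 0, 2)), rnorm(n0))
    lab <- c(rep(TRUE, n1), rep(FALSE, n0))
    auc <- roc_auc(resp, lab)$auc
    mw <- mean(outer(resp[lab], resp[!lab], `>`) +
                 0.5 * outer(resp[lab], resp[!lab], `==`))
    maxdiff <- max(maxdiff, abs(auc - mw))
  }
  expect_lte(maxdiff, 0.02 + 1e-9)
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(7)
  resp <- rnorm(300); lab <- resp + rnorm(300) > 0
  a1 <- roc_auc(resp, lab)$auc
  a2 <- roc_auc(exp(resp), lab)$auc
  expect_lt(abs(a1 - a2), 0.02)
})

test_that("velocity-to-pixel conversion matches the trajectory geometry", {
  expect_equal(px_per_frame(50), 4L)
  expect_equal(px_per_frame(150), 12L)
  expect_equal(px_per_frame(250), 20L)
  expect_equal(px_per_frame(350), 28L)
})

test_that("transition stimuli have 60 frames and labelled crossings", {
  sc <- generate_scene(seed = 1)
  for (v in c(50, 150, 250, 350)) {
    stims <- simulate_transitions(sc, v)
    expect_length(stims, 4)
    types <- vapply(stims, `[[`, "", "transition_type")
    expect_setequal(types, c("sky-to-sky", "sky-to-ground",
                             "ground-to-ground", "ground-to-sky"))
    for (st in stims) {
      expect_equal(dim(st$frames), c(2, 60, 18, 16))
      expect_equal(st$px_per_frame, px_per_frame(v))
      expect_true(st$t0 >= 1 && st$t0 <= 60)
    }
  }
  expect_error(simulate_transitions(sc, 99), "velocity")
  s99 <- simulate_transitions(sc, 99, free_velocity = TRUE)
  expect_length(s99, 4)
})

test_that("clockwise and counterclockwise traversals are temporal mirrors", {
  sc <- generate_scene(seed = 2, texture_amp = 0)   # uniform regions
  cw <- simulate_transitions(sc, 250, "clockwise")
  ccw <- simulate_transitions(sc, 250, "counterclockwise")
  ## matching edges: cw sky-to-ground reverses to ccw ground-to-sky
  get <- function(l, ty) l[[which(vapply(l, `[[`, "", "transition_type") == ty)]]
  a <- get(cw, "sky-to-ground")$frames
  b <- get(ccw, "ground-to-sky")$frames
  expect_equal(a, b[, 60:1, , ], tolerance = 1e-12)
})

test_that("sky/ground scenes have opponent chromatic statistics", {
  sc <- generate_scene(seed = 3)
  top <- sc$scene[, seq_len(sc$horizon), ]
  bot <- sc$scene[, (sc$horizon + 1):dim(sc$scene)[2], ]
  expect_gt(mean(top[2, , ]) - mean(top[1, , ]), 0)   # sky: UV > green
  expect_lt(mean(bot[2, , ]) - mean(bot[1, , ]), 0)   # ground: green > UV
})

test_that("group tuning maps bin contrasts with masked empty bins", {
  ev <- data.frame(gamma_green = c(-0.1, -0.1, 0.1),
                   gamma_uv = c(0.1, 0.1, -0.1))
  gm <- group_tuning_map(ev, c(1, 3, 5), bins = 10,
                         box = list(xlim = c(-0.2, 0.2),
                                    ylim = c(-0.2, 0.2)))
  expect_equal(length(gm$map), 100)
  expect_equal(sum(!is.na(gm$map)), 2)
  expect_equal(gm$map[gm$counts == 2], 2)     # mean of 1 and 3
  ## all events in one bin
  ev1 <- data.frame(gamma_green = rep(0.05, 4), gamma_uv = rep(0.05, 4))
  gm1 <- group_tuning_map(ev1, rep(2, 4), bins = 10,
                          box = list(xlim = c(-1, 1), ylim = c(-1, 1)))
  expect_equal(sum(!is.na(gm1$map)), 1)
})
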