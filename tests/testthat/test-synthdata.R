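test_that("generated movies respect clip structure and intensity range", {
  mv <- small_movie()
  cfg <- mv$config
  expect_equal(length(mv$clip_ids) %% cfg$clip_len, 0L)
  expect_equal(length(mv$test_clip_ids), cfg$n_test)
  expect_equal(mv$n_test_presentations, 3L)
  for (id in unique(mv$clip_ids)) {
    for (ci in 1:2) {
      cm <- mean(mv$frames[ci, mv$clip_ids == id, , ])
      expect_gte(cm, cfg$mean_range[1] - 1e-9)
      expect_lte(cm, cfg$mean_range[2] + 1e-9)
    }
  }
  ## all training frames inside the recorded intensity range, by construction
  tr <- mv$clip_ids %in% names(mv$split)[mv$split != "test"]
  expect_gte(min(mv$frames[1, tr, , ]), mv$intensity_range["green", "min"])
  expect_lte(max(mv$frames[2, tr, , ]), mv$intensity_range["uv", "max"])
})

test_that("sky clips are UV-dominant and ground clips green-dominant at any seed", {
  for (seed in c(0, 3, 11)) {
    mv <- generate_movie(movie_config(n_clips = 10, n_validation = 2),
                         seed = seed)
    dm <- mv$clip_means[, "uv"] - mv$clip_means[, "green"]
    expect_true(all(dm[mv$clip_labels == "sky"] > 0))
    expect_true(all(dm[mv$clip_labels == "ground"] < 0))
  }
})

test_that("zero texture amplitude gives flat frames at the clip mean", {
  mv <- generate_movie(movie_config(n_clips = 8, n_validation = 1,
                                    texture_amp = 0), seed = 1)
  id <- mv$clip_ids[1]
  fr <- mv$frames[1, mv$clip_ids == id, , ]
  expect_equal(max(fr) - min(fr), 0)
  expect_equal(mean(fr), unname(mv$clip_means[id, "green"]))
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- movie_config(n_clips = 8, n_validation = 1)
  m1 <- generate_movie(cfg, seed = 5)
  m2 <- generate_movie(cfg, seed = 5)
  expect_identical(m1$frames, m2$frames)
  expect_identical(m1$clip_labels, m2$clip_labels)
  p1 <- generate_population(population_config(), seed = 3)
  p2 <- generate_population(population_config(), seed = 3)
  expect_identical(p1, p2)
  mv <- small_movie()
  r1 <- simulate_recording(p1[1:3], mv, seed = 9)
  r2 <- simulate_recording(p2[1:3], mv, seed = 9)
  expect_identical(r1$traces, r2$traces)
})

test_that("movie config errors when no test set can be formed", {
  expect_error(generate_movie(movie_config(n_clips = 5), seed = 0),
               "test set")
  expect_error(population_config(families = integer(0)), "non-empty")
})

test_that("population invariants hold: unit-norm filters, opponent signs", {
  cells <- generate_population(population_config(
    families = c(`opponent-SbC` = 5)), seed = 1)
  expect_length(cells, 5)
  for (cl in cells) {
    expect_equal(l2norm(cl$spatial_filter$green), 1, tolerance = 1e-9)
    expect_equal(l2norm(cl$spatial_filter$uv), 1, tolerance = 1e-9)
    expect_equal(l2norm(cl$temporal_filter$green), 1, tolerance = 1e-9)
    expect_true(sign(cl$chromatic_weights["green"]) !=
                  sign(cl$chromatic_weights["uv"]))
    expect_true(cl$rf_location["x"] >= 1 && cl$rf_location["x"] <= 16)
    expect_true(cl$rf_location["y"] >= 1 && cl$rf_location["y"] <= 18)
  }
})

test_that("opponent cells prefer UV-ON/green-OFF over UV-ON/green-ON", {
  cells <- Filter(function(c) c$family == "opponent-SbC",
                  small_population())
  for (cl in cells) {
    r_off <- probe_fullfield_step(cl, green_dir = -1, uv_dir = 1)
    r_on <- probe_fullfield_step(cl, green_dir = 1, uv_dir = 1)
    expect_gt(r_off, r_on)
  }
})

test_that("noiseless identity-kernel recording reproduces resampled rates", {
  mv <- small_movie()
  cells <- small_population()[1:2]
  pack <- simulate_recording(cells, mv, seed = 0, calcium = "identity",
                             drift_amp = 0, noise_level = 0, pre_stim_s = 0)
  ## trace samples are linear interpolations of the 30 Hz rates at 7.8125 Hz
  fr <- mv$frame_rate
  r <- pack$rates[1, ]
  tt <- (seq_len(ncol(pack$traces)) - 1) / pack$trace_rate
  expected <- approx((seq_along(r) - 1) / fr, r, xout = tt)$y
  expect_close(pack$traces[1, ], expected, 1e-9)
})

test_that("test repeats of a noiseless cell are identical (QI = 1)", {
  pack <- small_recording()
  qi <- quality_index(t(pack$test_repeats[1, , ]))
  expect_equal(qi, 1, tolerance = 1e-12)
})
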