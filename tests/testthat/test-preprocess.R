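test_that("detrending removes slow drift and normalises by baseline SD", {
  rate <- TRACE_RATE
  n <- round(rate * 400)
  t0 <- round(rate * 30)
  slopes <- numeric(20)
  for (s in seq_len(20)) {
    set.seed(s)
    tt <- seq_len(n)
    slope_in <- 0.01
    raw <- slope_in * tt + rnorm(n, 0, 1)
    dt <- detrend_trace(raw, sampling_rate = rate, t0 = t0)
    fit <- lm(dt$values ~ tt)                     # independent slope oracle
    slopes[s] <- abs(coef(fit)[2]) / slope_in
  }
  expect_lt(mean(slopes), 0.01)       # ramp removed to < 1% of input slope
  ## after clipping at the 2.5th percentile the trace is non-negative
  expect_gte(min(dt$values), 0)
  ## provenance records the filter settings
  expect_equal(dt$window_s, 60)
  expect_equal(dt$poly_order, 3L)
})

test_that("detrending rejects degenerate traces", {
  expect_error(detrend_trace(rep(1, 5000), t0 = 100), "constant")
  ## zero pre-stimulus SD: constant baseline, active afterwards
  x <- c(rep(0, 1000), rnorm(3000))
  expect_error(detrend_trace(x, t0 = 150), "pre-stimulus")
})

test_that("detrending is near-idempotent when drift is absent", {
  set.seed(3)
  x <- abs(rnorm(4000)) + 0.5
  d1 <- detrend_trace(x, t0 = 200)
  d2 <- detrend_trace(d1$values, t0 = 200)
  ## second application changes values only through the percentile re-offset
  r <- d2$values * d2$baseline_sd + d2$eta_2_5
  expect_lt(sd(r - d1$values) / sd(d1$values), 0.05)
})

test_that("rate inference inverts a known calcium convolution", {
  fr <- FRAME_RATE
  tt <- seq(0, 120, by = 1 / fr)
  rate_true <- pmax(sin(2 * pi * 0.2 * tt), 0) + 0.2
  tau <- 1.0
  L <- ceiling(5 * tau * fr)
  k <- exp(-(0:(L - 1)) / (tau * fr)); k <- k / sum(k)
  conv <- as.numeric(stats::filter(c(rep(0, L - 1), rate_true), k,
                                   sides = 1))[L:(L + length(rate_true) - 1)]
  trace <- approx((seq_along(conv) - 1) / fr, conv,
                  xout = seq(0, 119.9, by = 1 / TRACE_RATE))$y
  r <- infer_rates(trace, "nonneg_deconvolution", calcium_tau = tau)
  n <- min(length(r), length(rate_true))
  expect_gte(cor(r[10:n], rate_true[10:n]), 0.99)
  expect_true(all(r >= 0))
})

test_that("rate inference handles passthrough and zero traces", {
  gt <- c(0, 1, 2, 1, 0)
  expect_equal(infer_rates(NULL, "ground_truth_passthrough",
                           ground_truth = gt), gt)
  expect_true(all(infer_rates(rep(0, 100), "nonneg_deconvolution") == 0))
  expect_error(infer_rates(rnorm(10), "nearest_neighbour"))
})

test_that("quality index: identical repeats 1, iid noise 1/I, shift-invariant", {
  set.seed(11)
  r <- matrix(rep(rnorm(200), 3), 200, 3)
  expect_equal(quality_index(r), 1, tolerance = 1e-12)
  w <- matrix(rnorm(10000 * 3), 10000, 3)
  expect_equal(quality_index(w), 1 / 3, tolerance = 0.02)
  expect_equal(quality_index(w + 5), quality_index(w))
  expect_warning(q0 <- quality_index(matrix(1, 10, 3)), "flat")
  expect_equal(q0, 0)
})

test_that("inclusion filters apply the documented thresholds step by step", {
  thr <- inclusion_thresholds()
  ## hand-set metrics straddling each threshold; expected masks enumerated
  ## by hand below
  report <- data.frame(
    qi_mb = c(0.9, 0.5, 0.7, 0.61, 0.59, 0.9, 0.9, 0.9, 0.9, 0.9),
    qi_chirp = c(0.9, 0.30, 0.36, 0.2, 0.36, 0.9, 0.9, 0.9, 0.9, 0.9),
    classifier_confidence = c(1, 1, 0.25, 0.24, 1, 0.2, 0.25, 1, 1, 1),
    test_corr_single_trial = c(1, 1, 1, 1, 1, 1, 0.3, 0.31, 0.29, 1),
    dog_cost_green = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.109,
                       0.05, 0.11),
    dog_cost_uv = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05,
                    0.05))
  m <- apply_inclusion_filters(report, thr)
  ## step 1: QI_MB > 0.6 OR QI_chirp > 0.35
  expect_equal(unname(m[, "step1"]),
               c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
  ## steps 2-3: confidence >= 0.25 (inclusive), cumulative with step 1
  expect_equal(unname(m[, "step3"]),
               c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE,
                 TRUE))
  ## step 4: single-trial correlation > 0.3 (strict)
  expect_equal(unname(m[, "step4"]),
               c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE,
                 TRUE))
  ## step 5: DoG cost < 0.11 in both channels
  expect_equal(unname(m[, "step5"]),
               c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE,
                 FALSE))
  ## masks are monotone non-increasing across steps
  for (j in 2:ncol(m)) expect_true(all(m[, j] <= m[, j - 1]))
})

test_that("inclusion filters pass maximal reports and name missing fields", {
  best <- data.frame(qi_mb = 1, qi_chirp = 1, classifier_confidence = 1,
                     test_corr_single_trial = 1, dog_cost_green = 0,
                     dog_cost_uv = 0)
  expect_true(all(apply_inclusion_filters(best)))
  expect_error(apply_inclusion_filters(best[, 1:2], steps = 4), "step 4")
})
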