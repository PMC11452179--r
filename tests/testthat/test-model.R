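test_that("forward pass enforces the input contract", {
  m <- init_model(2, seed = 1)
  expect_error(twin_forward(m, array(0, dim = c(100, 50, 1))), "18 x 16")
  expect_error(twin_forward(m, array(0, dim = c(576, 20, 1))),
               "temporal support")
})

test_that("zero input with zero biases gives a constant softplus(0) output", {
  m <- init_model(2, seed = 1)
  m$params$b0 <- rep(0, 2)
  m$params$be1 <- rep(0, 16); m$params$be2 <- rep(0, 16)
  m$state <- list(rm1 = rep(0, 16), rv1 = rep(1, 16),
                  rm2 = rep(0, 16), rv2 = rep(1, 16))
  fw <- twin_forward(m, array(0, dim = c(576, 50, 1)))
  expect_close(fw$y, softplus(0), 1e-12)
})

test_that("the LN variant is linear before the softplus", {
  m <- ln_probe_model()
  set.seed(2)
  x <- array(rnorm(576 * 50), dim = c(576, 50, 1))
  y <- array(rnorm(576 * 50), dim = c(576, 50, 1))
  z <- array(0, dim = c(576, 50, 1))
  pre <- function(v) twin_forward(m, v)$pre
  expect_close(pre(x + y), pre(x) + pre(y) - pre(z), 1e-6)
  ## doubling feature weights while halving second-layer kernels leaves the
  ## output unchanged (linear composition, neutral normalisation)
  m2 <- m
  m2$params$wf <- 2 * m$params$wf
  m2$params$W2 <- m$params$W2 / 2
  m2$params$a2 <- m$params$a2       # temporal part untouched
  expect_close(twin_forward(m2, x)$pre, pre(x), 1e-8)
})

test_that("the CNN variant fails superposition (it is nonlinear)", {
  m <- init_model(3, twin_arch("elu"), seed = 3)
  set.seed(4)
  x <- array(rnorm(576 * 50, 0, 2), dim = c(576, 50, 1))
  y <- array(rnorm(576 * 50, 0, 2), dim = c(576, 50, 1))
  z <- array(0, dim = c(576, 50, 1))
  pre <- function(v) twin_forward(m, v)$pre
  expect_gt(max(abs(pre(x + y) - (pre(x) + pre(y) - pre(z)))), 1e-4)
})

test_that("stored kernels are space-time separable by construction", {
  m <- init_model(1, seed = 5)
  K1 <- temporal_kernel(m$params$a1, m$params$b1, L = 21, tau = m$params$tau)
  ## full 3D kernel of feature f is the outer product spatial x temporal:
  ## its unfolding has rank 1 exactly
  f <- 3
  full <- outer(m$params$W1[, f], K1[, f])
  expect_equal(qr(full)$rank, 1L)
})

test_that("ensemble prediction is the arithmetic mean of member outputs", {
  mv <- small_movie()
  members <- lapply(1:3, function(s) {
    m <- init_model(2, seed = s)
    m$norm <- list(mean = c(green = 0.1, uv = 0.1),
                   sd = c(green = 0.05, uv = 0.05),
                   zrange = rbind(green = c(min = -3, max = 3),
                                  uv = c(min = -3, max = 3)))
    m$trained <- TRUE
    m
  })
  ens <- structure(list(members = members, arch = members[[1]]$arch,
                        n_neurons = 2, norm = members[[1]]$norm),
                   class = "twin_ensemble")
  set.seed(6)
  x <- array(rnorm(576 * 50), dim = c(576, 50, 1))
  ys <- lapply(members, function(m) twin_forward(m, x)$y)
  expect_close(ensemble_forward(ens, x), Reduce(`+`, ys) / 3, 1e-12)
})

test_that("Poisson loss: unit case, minimiser, stationarity", {
  pred <- matrix(1, 4, 25)
  expect_equal(poisson_loss(pred, pred), 100)   # 1 - 1*log(1) = 1 per term
  expect_error(poisson_loss(matrix(0, 2, 2), matrix(1, 2, 2)), "positive")
  ## 1-D numeric minimisation oracle: argmin over a constant prediction is
  ## the mean of the targets
  set.seed(7)
  target <- rexp(50)
  f <- function(r) poisson_loss(rep(r, 50), target)
  opt <- optimize(f, c(1e-3, 10))
  expect_equal(opt$minimum, mean(target), tolerance = 1e-4)
  ## gradient 1 - r/r_hat vanishes at r_hat = r
  expect_close(poisson_loss_grad(target + 1e-12, target), 0, 1e-9)
})

test_that("training is deterministic given the seed", {
  mv <- generate_movie(movie_config(n_clips = 10, n_validation = 1), seed = 2)
  cells <- small_population()[c(1, 3)]
  pack <- simulate_recording(cells, mv, seed = 0, noise_level = 0,
                             drift_amp = 0)
  sch <- train_schedule(max_epochs = 2, n_cycles = 1, patience = 2,
                        batch_size = 8, n_members = 1)
  m1 <- train_twin(mv, pack$rates, twin_arch("elu"), sch, seed = 11)
  m2 <- train_twin(mv, pack$rates, twin_arch("elu"), sch, seed = 11)
  expect_identical(m1$params, m2$params)
  expect_false(identical(
    m1$params$W1,
    train_twin(mv, pack$rates, twin_arch("elu"), sch, seed = 12)$params$W1))
})

test_that("evaluation scores perfect and inverted predictions correctly", {
  mv <- small_movie()
  cells <- small_population()[1:2]
  pack <- simulate_recording(cells, mv, seed = 1, noise_level = 0.2,
                             drift_amp = 0)
  ti <- test_frame_indices(mv)
  sup <- 30L
  ## fabricate a "model" whose prediction equals the repeat average
  reps <- array(0, dim = c(2, 3, length(ti)))
  for (n in 1:2) for (i in 1:3)
    reps[n, i, ] <- infer_rates(pack$test_repeats[n, i, ],
                                "nonneg_deconvolution", n_out = length(ti))
  avg <- apply(reps, c(1, 3), mean)
  fake <- list(predict = avg[, (sup + 1):length(ti), drop = FALSE])
  ## direct check of the two metrics on hand-made predictions
  c2m <- pearson(fake$predict[1, ], avg[1, (sup + 1):length(ti)])
  expect_equal(as.numeric(c2m), 1)
  inv <- pearson(-fake$predict[1, ] + 2, avg[1, (sup + 1):length(ti)])
  expect_equal(as.numeric(inv), -1)
})
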