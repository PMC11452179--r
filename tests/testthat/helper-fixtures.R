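## Shared fixtures, memoised per test session. Everything is generated in
## code at fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, fn) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fn()
  .fixtures[[name]]
}

## A small movie shared by fast tests.
small_movie <- function() {
  memo("small_movie", function()
    generate_movie(movie_config(n_clips = 14, n_validation = 2), seed = 0))
}

## A small mixed population (with opponent cells), noiseless.
small_population <- function() {
  memo("small_population", function()
    generate_population(population_config(
      families = c(`ON` = 2, `OFF` = 2, `ON-OFF` = 2, `slow-ON` = 2,
                   `opponent-SbC` = 2),
      noise_level = 0), seed = 1))
}

small_recording <- function() {
  memo("small_recording", function()
    simulate_recording(small_population(), small_movie(), seed = 2,
                       noise_level = 0, drift_amp = 0))
}

## A hand-built linearised (LN) model in evaluation mode, used for
## closed-form MEI and superposition tests. Weights are random but fixed;
## batch-norm runs on neutral statistics so the pre-softplus map is exactly
## linear in the input.
ln_probe_model <- function(wide_range = TRUE) {
  m <- init_model(3, twin_arch("identity"), seed = 7)
  m$state <- list(rm1 = rep(0, 16), rv1 = rep(1, 16),
                  rm2 = rep(0, 16), rv2 = rep(1, 16))
  m$params$be1 <- rep(0, 16); m$params$be2 <- rep(0, 16)
  ## scale the readout so gradients are of usable size, and push the bias
  ## deep into the softplus's linear range so the objective is an exactly
  ## linear functional of the input (the closed-form optimum then holds
  ## exactly, not just approximately)
  m$params$wf <- 40 * m$params$wf
  m$params$b0 <- rep(200, length(m$params$b0))
  m$trained <- TRUE
  rng <- if (wide_range) c(-100, 100) else c(-1, 1)
  m$norm <- list(mean = c(green = 0.1, uv = 0.1),
                 sd = c(green = 0.05, uv = 0.05),
                 zrange = rbind(green = c(min = rng[1], max = rng[2]),
                                uv = c(min = rng[1], max = rng[2])))
  m
}

## The full linear filter of a model neuron of an LN model: gradient of the
## windowed mean response w.r.t. the input (constant for a linear map).
ln_linear_filter <- function(model, neuron, Tn = 50L) {
  x0 <- array(0, dim = c(CANVAS_H * CANVAS_W * N_CHAN, Tn, 1L))
  ob <- mei_objective(model, x0, neuron)
  ob$gx[, , 1]
}

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
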