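## The shared reduced-scale study used by the slower tests: one noiseless
## mixed population (linear-nonlinear families plus nonlinearly
## colour-opponent cells), one movie, a CNN twin and its LN control trained
## once per test session and reused. Sizes are chosen so the full training
## fits comfortably in CPU minutes; the methods vignette documents them.

study_movie_config <- function() movie_config(n_clips = 28, n_validation = 4)

study_families <- function() c(`ON` = 8, `OFF` = 8, `slow-ON` = 6,
                               `ON-OFF` = 4, `opponent-SbC` = 10)

study_schedule <- function(max_epochs = 60L) {
  train_schedule(patience = 4, n_cycles = 3, chunk_stride = 25,
                 max_epochs = max_epochs, n_members = 1)
}

study_data <- function() {
  memo("study_data", function() {
    mv <- generate_movie(study_movie_config(), seed = 0)
    cells <- generate_population(population_config(
      families = study_families(), noise_level = 0), seed = 1)
    pack <- simulate_recording(cells, mv, seed = 2, noise_level = 0,
                               drift_amp = 0)
    list(mv = mv, cells = cells, pack = pack,
         family = vapply(cells, `[[`, "", "family"))
  })
}

study_cnn <- function() {
  memo("study_cnn", function() {
    d <- study_data()
    train_ensemble(d$mv, d$pack$rates, twin_arch("elu"), study_schedule(),
                   seed = 0)
  })
}

study_ln <- function() {
  memo("study_ln", function() {
    d <- study_data()
    train_ensemble(d$mv, d$pack$rates, twin_arch("identity"),
                   study_schedule(), seed = 0)
  })
}

## MEIs and properties of the opponent and (fast/slow) ON cells under a model.
study_meis <- function(which = c("cnn", "ln")) {
  which <- match.arg(which)
  memo(paste0("study_meis_", which), function() {
    d <- study_data()
    sel <- c(which(d$family == "opponent-SbC"),
             which(d$family %in% c("ON", "slow-ON"))[1:6])
    model <- if (which == "cnn") study_cnn() else study_ln()
    meis <- synthesize_meis(model, sel, opts = list(seed = 5))
    props <- lapply(meis, mei_properties)
    list(neurons = sel, meis = meis, props = props,
         family = d$family[sel])
  })
}

## Test repeats as 30 Hz rate estimates (deconvolved per repeat).
study_test_repeats <- function() {
  memo("study_test_repeats", function() {
    d <- study_data()
    pack <- d$pack
    Tt <- length(pack$test_frames)
    N <- dim(pack$test_repeats)[1]
    nrep <- dim(pack$test_repeats)[2]
    reps <- array(0, dim = c(N, nrep, Tt))
    for (n in seq_len(N)) for (i in seq_len(nrep)) {
      reps[n, i, ] <- infer_rates(pack$test_repeats[n, i, ],
                                  "nonneg_deconvolution",
                                  calcium_tau = pack$calcium_tau,
                                  n_out = Tt)
    }
    reps
  })
}
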