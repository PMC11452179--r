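## Shared configuration for the numbered analysis scripts. All stages cache
## their artefacts under scratch/pipeline (not part of the deliverable) and
## write their result tables to results/.
##
## Scale: the simulated study uses a 28-clip movie (5 test, 4 validation)
## and a 36-cell population, trained with a single-member ensemble for 60
## epochs -- sizes at which the full workflow runs in CPU minutes while
## every qualitative result of the pipeline (receptive-field recovery,
## chromatic opponency of MEIs, CNN-vs-LN contrast, ground-to-sky detection)
## is reproduced. The movie generator's defaults (113 clips etc.) remain the
## reference conditions; see the methods vignette.

library(rgctwin)

analysis_config <- function() {
  pipeline_config(
    movie = movie_config(n_clips = 28, n_validation = 4),
    population = population_config(
      families = c(`ON` = 8, `OFF` = 8, `slow-ON` = 6, `ON-OFF` = 4,
                   `opponent-SbC` = 10),
      noise_level = 0),
    schedule = train_schedule(patience = 4, n_cycles = 3, chunk_stride = 25,
                              max_epochs = 60, n_members = 1),
    seed = 1,
    n_mei_cells = 12L,
    velocities = c(50, 150, 250, 350),
    n_scenes = 6L)
}

analysis_workdir <- function() {
  wd <- file.path("scratch", "pipeline")
  dir.create(wd, showWarnings = FALSE, recursive = TRUE)
  wd
}

results_dir <- function() {
  rd <- "results"
  dir.create(rd, showWarnings = FALSE)
  rd
}
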