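## Orchestration: stage-to-stage contracts, artefact caching keyed by config
## hashes, and invariant validation. The numbered scripts under analysis/
## drive these stages one by one; run_pipeline() runs them as one unit.

#' Default pipeline configuration
#'
#' One configuration tree for all stages. The movie and population blocks
#' are the study conditions (see [movie_config()], [population_config()]);
#' the schedule block sizes the training run.
#'
#' @param movie a [movie_config()]
#' @param population a [population_config()]
#' @param schedule a [train_schedule()]
#' @param seed master seed; stage seeds derive from it
#' @param rate_method rate-inference method for preprocessing
#' @param n_mei_cells cap on cells taken to MEI synthesis
#' @param mei_opts options passed to [synthesize_meis()]
#' @param velocities simulated-transition velocities
#' @param n_scenes scenes per velocity for simulated detection
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(movie = movie_config(),
                            population = population_config(),
                            schedule = train_schedule(),
                            seed = 1L,
                            rate_method = "ground_truth_passthrough",
                            n_mei_cells = 12L,
                            mei_opts = list(),
                            velocities = c(50, 150, 250, 350),
                            n_scenes = 10L) {
  cfg <- list(movie = movie, population = population, schedule = schedule,
              seed = as.integer(seed), rate_method = rate_method,
              n_mei_cells = as.integer(n_mei_cells), mei_opts = mei_opts,
              velocities = velocities, n_scenes = as.integer(n_scenes))
  class(cfg) <- "pipeline_config"
  cfg
}

## Content hash of any R object (md5 of its serialisation).
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

pipeline_stages <- function() {
  c("synthdata", "preprocess", "train", "mei", "detect", "stats")
}

stage_deps <- function() {
  list(synthdata = character(0),
       preprocess = "synthdata",
       train = c("synthdata", "preprocess"),
       mei = c("synthdata", "train"),
       detect = c("synthdata", "preprocess"),
       stats = "detect")
}

## Config slice that determines a stage's output (changing anything else
## leaves the stage up to date).
stage_config <- function(config, stage) {
  switch(stage,
    synthdata = config[c("movie", "population", "seed")],
    preprocess = config[c("movie", "population", "seed", "rate_method")],
    train = config[c("movie", "population", "seed", "rate_method",
                     "schedule")],
    mei = config[c("movie", "population", "seed", "rate_method", "schedule",
                   "n_mei_cells", "mei_opts")],
    detect = config[c("movie", "population", "seed", "rate_method",
                      "velocities", "n_scenes")],
    stats = config[c("movie", "population", "seed", "rate_method",
                     "velocities", "n_scenes")])
}

run_stage <- function(stage, config, art) {
  switch(stage,
    synthdata = {
      movie <- generate_movie(config$movie, seed = config$seed)
      cells <- generate_population(config$population, seed = config$seed + 1L)
      pack <- simulate_recording(cells, movie, seed = config$seed + 2L)
      list(movie = movie, cells = cells, pack = pack)
    },
    preprocess = {
      pack <- art$synthdata$pack
      rates <- if (config$rate_method == "ground_truth_passthrough")
        pack$rates
      else t(vapply(seq_len(nrow(pack$traces)), function(n) {
        dt <- detrend_trace(pack$traces[n, ], t0 = pack$t0)
        r <- infer_rates(dt, "nonneg_deconvolution",
                         calcium_tau = pack$calcium_tau)
        r[seq_len(ncol(pack$rates))]
      }, numeric(ncol(pack$rates))))
      report <- quality_report(pack)
      list(rates = rates, report = report)
    },
    train = {
      movie <- art$synthdata$movie
      rates <- art$preprocess$rates
      cnn <- train_ensemble(movie, rates, twin_arch("elu"),
                            config$schedule, seed = config$seed + 10L)
      ln <- train_ensemble(movie, rates, twin_arch("identity"),
                           config$schedule, seed = config$seed + 10L)
      ev_cnn <- evaluate_model(cnn, movie, test_rate_repeats(art))
      ev_ln <- evaluate_model(ln, movie, test_rate_repeats(art))
      list(cnn = cnn, ln = ln, eval_cnn = ev_cnn, eval_ln = ev_ln)
    },
    mei = {
      sel <- seq_len(min(config$n_mei_cells,
                         length(art$synthdata$cells)))
      meis <- synthesize_meis(art$train$cnn, sel,
                              opts = utils::modifyList(
                                list(seed = config$seed + 20L),
                                config$mei_opts))
      props <- lapply(meis, mei_properties)
      list(neurons = sel, meis = meis, properties = props)
    },
    detect = {
      movie <- art$synthdata$movie
      events <- find_transitions(movie)
      movie_auc <- detection_auc(events, art$preprocess$rates)
      movie_auc$family <- vapply(art$synthdata$cells,
                                 function(c) c$family, "")
      sim_auc <- simulated_detection(art$synthdata$cells,
                                     config$velocities,
                                     n_scenes = config$n_scenes,
                                     seed = config$seed + 30L)
      list(events = events, movie_auc = movie_auc, sim_auc = sim_auc)
    },
    stats = {
      auc <- art$detect$movie_auc
      fams <- unique(auc$family)
      cmp <- list()
      for (f1 in fams) for (f2 in fams) if (f1 < f2) {
        a <- auc$auc[auc$family == f1]; b <- auc$auc[auc$family == f2]
        if (length(a) >= 4 && length(b) >= 4) {
          pt <- permutation_test(a, b, n_perm = 10000L,
                                 seed = config$seed + 40L)
          cmp[[paste(f1, f2, sep = "_vs_")]] <-
            data.frame(group1 = f1, group2 = f2,
                       delta_auc = pt$observed, p_value = pt$p_value,
                       cohens_d = cohens_d(a, b))
        }
      }
      do.call(rbind, cmp)
    })
}

test_rate_repeats <- function(art) {
  pack <- art$synthdata$pack
  ## repeats as 30 Hz rates: passthrough uses ground truth for each repeat
  ## trace via deconvolution-free resampling of the trace itself
  nrep <- dim(pack$test_repeats)[2]
  Tt <- length(pack$test_frames)
  N <- dim(pack$test_repeats)[1]
  reps <- array(0, dim = c(N, nrep, Tt))
  for (n in seq_len(N)) for (i in seq_len(nrep)) {
    reps[n, i, ] <- infer_rates(pack$test_repeats[n, i, ],
                                "nonneg_deconvolution",
                                calcium_tau = pack$calcium_tau, n_out = Tt)
  }
  reps
}

#' Run the pipeline
#'
#' Executes the stages in dependency order, caching each stage's artefact
#' (RDS) under `workdir` keyed by a hash of the configuration slice it
#' depends on; an up-to-date artefact is loaded instead of recomputed. A
#' manifest (JSON) records stage hashes, timestamps and wall-clock times.
#'
#' @param config a [pipeline_config()]
#' @param stages subset of stages to run (dependencies are pulled in)
#' @param workdir artefact directory
#' @param force recompute even if up to date
#' @return named list of stage artefacts (invisibly the manifest as
#'   attribute `manifest`)
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = pipeline_stages(),
                         workdir = tempfile("rgctwin_run_"),
                         force = FALSE) {
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  deps <- stage_deps()
  ## requested stages run; their dependencies are loaded from disk (a
  ## dependency is only recomputed if it was itself requested)
  order <- intersect(pipeline_stages(), stages)
  manifest_path <- file.path(workdir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::fromJSON(manifest_path, simplifyVector = FALSE) else list()
  art <- list()
  for (s in order) {
    for (d in deps[[s]]) if (is.null(art[[d]])) {
      f <- file.path(workdir, paste0(d, ".rds"))
      if (!file.exists(f)) stop("missing upstream artefact for stage '", s,
                                "': ", d)
      art[[d]] <- readRDS(f)
    }
    h <- config_hash(stage_config(config, s))
    f <- file.path(workdir, paste0(s, ".rds"))
    fresh <- !force && file.exists(f) &&
      identical(manifest[[s]]$hash, h)
    if (fresh) {
      art[[s]] <- readRDS(f)
      manifest[[s]]$recomputed <- FALSE
    } else {
      t0 <- Sys.time()
      art[[s]] <- run_stage(s, config, art)
      saveRDS(art[[s]], f)
      manifest[[s]] <- list(hash = h,
                            time = format(Sys.time(), tz = "UTC"),
                            wall_s = as.numeric(Sys.time() - t0,
                                                units = "secs"),
                            recomputed = TRUE)
    }
  }
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  attr(art, "manifest") <- manifest
  invisible(art)
}

#' Validate stored pipeline artefacts against the declared invariants
#'
#' Checks, per artefact present in `workdir`: movie clip-mean range and
#' sky/ground chromatic separation, test-set structure, population filter
#' normalisation and opponent sign structure, quality-index range,
#' inclusion-mask monotonicity, MEI norm-budget and range-box constraints.
#'
#' @param workdir pipeline artefact directory
#' @return data.frame with one row per invariant (`invariant`, `stage`,
#'   `pass`)
#' @export
validate_artifacts <- function(workdir) {
  res <- list()
  add <- function(stage, invariant, pass)
    res[[length(res) + 1L]] <<- data.frame(stage = stage,
                                           invariant = invariant,
                                           pass = isTRUE(pass))
  f <- file.path(workdir, "synthdata.rds")
  if (file.exists(f)) {
    sd <- readRDS(f)
    mv <- sd$movie
    cm <- vapply(unique(mv$clip_ids), function(id)
      mean(mv$frames[, mv$clip_ids == id, , ]), numeric(1))
    rng <- mv$config$mean_range
    add("synthdata", "clip_means_in_range",
        all(cm >= rng[1] - 1e-9 & cm <= rng[2] + 1e-9))
    lab <- mv$clip_labels
    dm <- mv$clip_means[, "uv"] - mv$clip_means[, "green"]
    add("synthdata", "sky_uv_positive", all(dm[lab == "sky"] > 0))
    add("synthdata", "ground_uv_negative", all(dm[lab == "ground"] < 0))
    add("synthdata", "test_block_size",
        length(mv$test_clip_ids) == mv$config$n_test)
    add("synthdata", "time_divisible_by_clip_length",
        length(mv$clip_ids) %% mv$clip_len == 0)
    norms <- vapply(sd$cells, function(cl)
      abs(l2norm(cl$spatial_filter$green) - 1) +
        abs(l2norm(cl$spatial_filter$uv) - 1), numeric(1))
    add("synthdata", "unit_norm_spatial_filters", all(norms < 1e-9))
    opp <- Filter(function(cl) cl$family == "opponent-SbC", sd$cells)
    add("synthdata", "opponent_sign_structure",
        all(vapply(opp, function(cl)
          sign(cl$chromatic_weights["green"]) !=
            sign(cl$chromatic_weights["uv"]), logical(1))))
  }
  f <- file.path(workdir, "preprocess.rds")
  if (file.exists(f)) {
    pp <- readRDS(f)
    add("preprocess", "qi_in_unit_interval",
        all(pp$report$qi_mb >= 0 & pp$report$qi_mb <= 1))
    add("preprocess", "rates_nonnegative", all(pp$rates >= 0))
  }
  f <- file.path(workdir, "mei.rds")
  if (file.exists(f)) {
    me <- readRDS(f)
    add("mei", "norm_budget",
        all(vapply(me$meis, function(m)
          mei_norm(m) <= m$b + 1e-6, logical(1))))
    add("mei", "range_box",
        all(vapply(me$meis, function(m) {
          zr <- m$zrange
          all(m$tensor[1, , , ] >= zr["green", "min"] - 1e-9) &&
            all(m$tensor[1, , , ] <= zr["green", "max"] + 1e-9) &&
            all(m$tensor[2, , , ] >= zr["uv", "min"] - 1e-9) &&
            all(m$tensor[2, , , ] <= zr["uv", "max"] + 1e-9)
        }, logical(1))))
  }
  f <- file.path(workdir, "detect.rds")
  if (file.exists(f)) {
    de <- readRDS(f)
    add("detect", "auc_in_unit_interval",
        all(de$movie_auc$auc >= 0 & de$movie_auc$auc <= 1))
  }
  do.call(rbind, res)
}
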