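#!/usr/bin/env Rscript
## Stage 1: generate the simulated study -- the dichromatic clip movie, the
## ground-truth RGC population, and the calcium-like recording. Writes
## summary tables of what was generated.

source(file.path("analysis", "00_config.R"))
cfg <- analysis_config()
art <- run_pipeline(cfg, stages = "synthdata", workdir = analysis_workdir())

mv <- art$synthdata$movie
cells <- art$synthdata$cells

clips <- data.frame(clip = seq_len(nrow(mv$clip_means)),
                    label = unname(mv$clip_labels),
                    split = unname(mv$split),
                    mean_green = mv$clip_means[, "green"],
                    mean_uv = mv$clip_means[, "uv"])
write.csv(clips, file.path(results_dir(), "movie_clips.csv"),
          row.names = FALSE)

pop <- do.call(rbind, lapply(cells, function(cl) data.frame(
  cell_id = cl$cell_id, family = cl$family,
  rf_x = cl$rf_location["x"], rf_y = cl$rf_location["y"],
  w_green = cl$chromatic_weights["green"],
  w_uv = cl$chromatic_weights["uv"])))
write.csv(pop, file.path(results_dir(), "population.csv"), row.names = FALSE)

cat(sprintf("movie: %d clips (%d test, %d validation), %d frames\n",
            length(mv$clip_labels), sum(mv$split == "test"),
            sum(mv$split == "validation"), length(mv$clip_ids)))
cat(sprintf("population: %d cells (%s)\n", length(cells),
            paste(names(table(pop$family)), table(pop$family),
                  sep = "=", collapse = ", ")))
cat(sprintf("sky clips have UV-green mean difference %+0.3f, ground %+0.3f\n",
            mean((mv$clip_means[, "uv"] -
                    mv$clip_means[, "green"])[mv$clip_labels == "sky"]),
            mean((mv$clip_means[, "uv"] -
                    mv$clip_means[, "green"])[mv$clip_labels == "ground"])))
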