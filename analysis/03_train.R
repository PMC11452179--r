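#!/usr/bin/env Rscript
## Stage 3: train the CNN digital twin and its linearised (LN) control,
## evaluate both on the repeated test sequence, and report the
## receptive-field recovery of the readouts.

source(file.path("analysis", "00_config.R"))
cfg <- analysis_config()
art <- run_pipeline(cfg, stages = c("synthdata", "preprocess", "train"),
                    workdir = analysis_workdir())

cells <- art$synthdata$cells
fam <- vapply(cells, `[[`, "", "family")
ev <- art$train$eval_cnn
ev$family <- fam
ev$corr_to_mean_ln <- art$train$eval_ln$corr_to_mean

tru <- t(vapply(cells, function(c) c$rf_location, numeric(2)))
est <- t(art$train$cnn$members[[1]]$params$mu)
ev$rf_error_px <- sqrt(rowSums((tru - est)^2))

write.csv(ev, file.path(results_dir(), "model_evaluation.csv"),
          row.names = FALSE)

cat(sprintf("CNN correlation to mean: %.3f (LN: %.3f)\n",
            mean(ev$corr_to_mean), mean(ev$corr_to_mean_ln)))
cat(sprintf("opponent cells, CNN vs LN: %.3f vs %.3f\n",
            mean(ev$corr_to_mean[fam == "opponent-SbC"]),
            mean(ev$corr_to_mean_ln[fam == "opponent-SbC"])))
cat(sprintf("readout location error: mean %.2f px, max %.2f px\n",
            mean(ev$rf_error_px), max(ev$rf_error_px)))
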