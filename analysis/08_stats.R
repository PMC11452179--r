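#!/usr/bin/env Rscript
## Stage 8: statistics on the detection results -- pairwise permutation
## tests on family AUC differences with Bonferroni correction, bootstrap
## confidence intervals, and effect sizes.

source(file.path("analysis", "00_config.R"))
cfg <- analysis_config()
art <- run_pipeline(cfg, stages = c("synthdata", "preprocess", "detect",
                                    "stats"),
                    workdir = analysis_workdir())

auc <- art$detect$movie_auc
fams <- unique(auc$family)
rows <- list()
for (f1 in fams) for (f2 in fams) if (f1 < f2) {
  a <- auc$auc[auc$family == f1]; b <- auc$auc[auc$family == f2]
  if (length(a) < 4 || length(b) < 4) next
  pt <- permutation_test(a, b, n_perm = 10000L, seed = cfg$seed)
  ci <- bootstrap_ci(list(a, b), function(x, y) mean(x) - mean(y),
                     n_boot = 100L, seed = cfg$seed)
  rows[[length(rows) + 1L]] <- data.frame(
    group1 = f1, group2 = f2,
    delta_auc = mean(a) - mean(b),
    p_value = pt$p_value,
    ci_low = ci$lower, ci_high = ci$upper,
    cohens_d = cohens_d(a, b))
}
tab <- do.call(rbind, rows)
m <- nrow(tab)
alpha <- bonferroni(0.05, m)
tab$significant <- tab$p_value < alpha
write.csv(tab, file.path(results_dir(), "stats.csv"), row.names = FALSE)

cat(sprintf("%d pairwise comparisons, Bonferroni-corrected alpha = %.4f\n",
            m, alpha))
opp <- tab[tab$group1 == "opponent-SbC" | tab$group2 == "opponent-SbC", ]
cat("opponent-SbC vs other families:\n")
print(opp[, c("group1", "group2", "delta_auc", "p_value", "cohens_d",
              "significant")], row.names = FALSE)
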