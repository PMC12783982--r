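#!/usr/bin/env Rscript
# Stage 4: population analyses. Builds per-genotype pseudopopulation
# spike-count matrices, computes within- vs cross-odour Euclidean
# distance distributions with a Welch omnibus test and Games-Howell
# post-hoc grid, then runs the subsampled PCA + Gaussian leave-one-
# trial-out decoder (and the kNN/ECOC control classifier) with per-size
# binomial chance tests, and compares genotype decoding curves.

library(odourpop)

out_dir <- "results"
seed <- 1L
iters <- 200L
sessions <- lapply(file.path("scratch/sessions", c("control", "mutant")),
                   read_session_bundle)
names(sessions) <- vapply(sessions, `[[`, "", "genotype")

pops <- lapply(sessions, build_pseudopopulation)

for (g in names(pops)) {
  ds <- cross_odour_distances(pops[[g]])
  cat(sprintf("%s distances: Welch F(%d, %.0f) = %.1f, p = %.3g\n",
              g, ds$omnibus$df[1], ds$omnibus$df[2], ds$omnibus$statistic,
              ds$omnibus$p))
  sig <- ds$grid < 0.05
  cat(sprintf("  %d / %d cross-vs-within comparisons significant (Games-Howell)\n",
              sum(sig, na.rm = TRUE), sum(!is.na(sig))))
  write.csv(ds$grid, file.path(out_dir, paste0("distance_grid_", g, ".csv")))
}

curves <- list()
for (g in names(pops)) {
  for (clf in c("gaussian", "knn_ecoc")) {
    cv <- decode_accuracy(pops[[g]], clf, iters = iters, seed = seed)
    curves[[paste(g, clf, sep = "_")]] <- cv
    top <- length(cv$sizes)
    cat(sprintf(
      "%s / %s: accuracy %.3f at %d units (chance 1/6, binomial p = %.3g)\n",
      g, clf, cv$accuracy[top], cv$sizes[top], cv$binomial_p[top]))
    write.csv(data.frame(size = cv$sizes, accuracy = cv$accuracy,
                         binomial_p = cv$binomial_p),
              file.path(out_dir, paste0("decoding_", g, "_", clf, ".csv")),
              row.names = FALSE)
  }
}

cmp <- compare_decoding_curves(curves$control_gaussian,
                               curves$mutant_gaussian)
write.csv(cmp, file.path(out_dir, "decoding_comparison.csv"),
          row.names = FALSE)
cat("\nControl vs mutant (Gaussian decoder), per population size:\n")
print(cmp)
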