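#!/usr/bin/env Rscript
# Stage 1: simulate one control and one mutant MOB recording session at
# study scale (100 units, 6 aldehydes x 19 trials, 500 ms stimulation)
# and write them to disk as plain-text session bundles.

library(odourpop)

seed <- 1L
out_dir <- "scratch/sessions"

for (g in c("control", "mutant")) {
  cfg <- genotype_preset(g, "MOB", n_units = 100, seed = seed)
  sim <- generate_session(cfg)
  path <- file.path(out_dir, g)
  write_session_bundle(sim$session, path, seed = seed)
  n_spikes <- sum(vapply(sim$session$units, function(u) {
    length(u$spike_times)
  }, numeric(1)))
  cat(sprintf(
    "%s: %d units, %d trials, %d spikes -> %s\n",
    g, length(sim$session$units), nrow(sim$session$trials), n_spikes, path))
  # keep the ground truth next to the bundle for later reference
  write.csv(sim$ground_truth$table,
            file.path(path, "ground_truth_synthetic.csv"),
            row.names = FALSE)
}
cat("Session bundles written under", out_dir, "\n")
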