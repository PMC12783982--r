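#!/usr/bin/env Rscript
# Stage 2: single-unit response analysis. Classifies every unit-odour
# pair by its mean odour-window z-score (threshold +-1.96), summarises
# responsive fractions per genotype, extracts response features (peak z,
# width, latency) for the excited pairs, and compares genotypes with the
# gated t / Mann-Whitney procedure. Also computes per-unit pairwise
# discriminability (d') summaries.

library(odourpop)

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)
sessions <- lapply(file.path("scratch/sessions", c("control", "mutant")),
                   read_session_bundle)
w <- analysis_windows()

labels <- do.call(rbind, lapply(sessions, classify_responses, windows = w))
frac <- response_fractions(labels)
write.csv(frac, file.path(out_dir, "response_fractions.csv"),
          row.names = FALSE)
cat("Responsive-unit fractions:\n")
print(frac[, c("genotype", "frac_responsive_units", "frac_excited_pairs",
               "frac_inhibited_pairs")])

# response features of excited unit-odour pairs, per genotype
features <- do.call(rbind, lapply(sessions, function(s) {
  lab <- classify_responses(s, w)
  exc <- lab[lab$label == "excited", ]
  if (nrow(exc) == 0) return(NULL)
  do.call(rbind, lapply(seq_len(nrow(exc)), function(i) {
    zr <- zscore_response(s, exc$unit_id[i], exc$odour_carbon[i], w)
    f <- peak_features(zr, "excited", w$feature_window)
    if (f$missing) return(NULL)
    data.frame(genotype = s$genotype, unit_id = exc$unit_id[i],
               odour_carbon = exc$odour_carbon[i], peak_z = f$peak_z,
               peak_width = f$peak_width, time_to_peak = f$time_to_peak)
  }))
}))
write.csv(features, file.path(out_dir, "excited_response_features.csv"),
          row.names = FALSE)

for (feat in c("peak_z", "peak_width", "time_to_peak")) {
  x <- features[features$genotype == "control", feat]
  y <- features[features$genotype == "mutant", feat]
  if (length(x) >= 3 && length(y) >= 3) {
    r <- compare_feature_distributions(x, y)
    cat(sprintf("%s: control median %.2f vs mutant %.2f (%s, p = %.3g)\n",
                feat, median(x), median(y), r$test, r$p))
  }
}

# per-unit discriminability
dps <- do.call(rbind, lapply(sessions, function(s) {
  dp <- unit_dprimes(s, w)$per_unit
  dp$genotype <- s$genotype
  dp
}))
write.csv(dps, file.path(out_dir, "unit_dprimes.csv"), row.names = FALSE)
for (col in c("mean_dprime", "max_dprime")) {
  r <- mann_whitney_u(dps[dps$genotype == "control", col],
                      dps[dps$genotype == "mutant", col])
  cat(sprintf("%s: control median %.2f vs mutant %.2f (Mann-Whitney U = %g, p = %.3g)\n",
              col, median(dps[dps$genotype == "control", col]),
              median(dps[dps$genotype == "mutant", col]), r$statistic, r$p))
}
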