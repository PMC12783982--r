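# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk.

# Minimal hand-built session: explicit spike times and trial table, no RNG.
# `spikes` is a list of numeric vectors (one per unit).
toy_session <- function(spikes, trials, genotype = "control",
                        region = "MOB", span = NULL) {
  units <- lapply(seq_along(spikes), function(i) {
    list(unit_id = i, tetrode_id = ((i - 1L) %/% 4L) + 1L,
         spike_times = sort(spikes[[i]]))
  })
  if (is.null(span)) span <- max(trials$offset_s) + 5
  structure(list(session_id = "toy", genotype = genotype, region = region,
                 span = span, units = units, trials = trials),
            class = "recording_session")
}

toy_trials <- function(carbons, onsets, duration = 0.5) {
  data.frame(trial_id = seq_along(onsets), odour_carbon = carbons,
             onset_s = onsets, offset_s = onsets + duration)
}

# Odour-independent Poisson pseudopopulation (null for decoder calibration):
# unit-specific rates drawn once, counts independent of odour identity.
null_population <- function(n_units = 60, n_trials = 19, seed = 1,
                            rate_log_mean = log(10), rate_log_sd = 0.6) {
  set.seed(seed)
  rates <- rlnorm(n_units, rate_log_mean, rate_log_sd)
  counts <- sapply(rates, function(r) rpois(6 * n_trials, r * 0.5))
  structure(list(counts = counts, odour = rep(3:8, each = n_trials),
                 trial_index = rep(seq_len(n_trials), 6), unit_key = NULL),
            class = "population_matrix")
}

# Six well-separated clusters: each odour drives its own block of units.
cluster_population <- function(n_units = 60, n_trials = 19, sep = 30,
                               noise_sd = 1, seed = 1) {
  set.seed(seed)
  per <- n_units %/% 6
  mu <- matrix(0, 6, n_units)
  for (i in 1:6) mu[i, ((i - 1) * per + 1):(i * per)] <- sep
  x <- mu[rep(1:6, each = n_trials), ] +
    matrix(rnorm(6 * n_trials * n_units, sd = noise_sd), 6 * n_trials,
           n_units)
  structure(list(counts = round(pmax(x, 0)),
                 odour = rep(3:8, each = n_trials),
                 trial_index = rep(seq_len(n_trials), 6), unit_key = NULL),
            class = "population_matrix")
}

# A z_response-shaped object with a prescribed z trace (for feature tests).
fake_zresponse <- function(z, centers = seq(0.05, by = 0.1,
                                            length.out = length(z))) {
  structure(list(unit_id = 1, odour_carbon = 3, center = centers,
                 rate = z, z = z, fr_baseline = 0, sd_baseline = 1,
                 mean_window_z = mean(z), label = "excited",
                 degenerate = FALSE),
            class = "z_response")
}

# Short-session generator config (fast to simulate in unit tests).
quick_config <- function(...) {
  args <- utils::modifyList(
    list(n_trials_per_odour = 2L, pre_onset_baseline = 2.5,
         inter_trial_interval = 4),
    list(...))
  do.call(generator_config, args)
}
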