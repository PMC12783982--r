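test_that("generation is deterministic given config and seed", {
  cfg <- quick_config(n_units = 4, seed = 5)
  g1 <- generate_session(cfg)
  g2 <- generate_session(cfg)
  expect_identical(g1, g2)
  g3 <- generate_session(quick_config(n_units = 4, seed = 6))
  expect_false(identical(g1$session$units, g3$session$units))
})

test_that("trial table has the designed layout", {
  g <- generate_session(generator_config(n_units = 2, seed = 3))
  tr <- g$session$trials
  expect_equal(nrow(tr), 6 * 19)
  expect_equal(as.vector(table(tr$odour_carbon)), rep(19, 6))
  expect_equal(tr$offset_s - tr$onset_s, rep(0.5, nrow(tr)))
  # non-overlapping, time ordered, baseline in-session
  expect_true(all(diff(tr$onset_s) > 0))
  expect_true(all(tr$onset_s[-1] >= tr$offset_s[-nrow(tr)]))
  expect_true(all(tr$onset_s >= 5.0))
  # spikes within session span, ascending
  for (u in g$session$units) {
    expect_true(all(u$spike_times >= 0 & u$spike_times < g$session$span))
    expect_false(is.unsorted(u$spike_times))
  }
})

test_that("rate_profile evaluates the excitation/suppression model", {
  gt <- list(unit_id = 1, baseline_rate = 5, responsive = TRUE,
             polarity = "excited", best_odour_carbon = 5,
             amplitude = setNames(2 * exp(-abs(3:8 - 5) / 1.5), 3:8),
             latency = 0.15, width = 0.3)
  # at the kernel peak of the best odour: b * (1 + A) = 15
  expect_equal(rate_profile(gt, 5, 0.15), 15)
  # before onset of the kernel support: baseline
  expect_equal(rate_profile(gt, 5, -0.2), 5)
  # flat tuning in the lambda -> Inf limit
  gt_flat <- gt
  gt_flat$amplitude[] <- 2 * exp(-abs(3:8 - 5) / Inf)
  rates <- vapply(3:8, function(oc) rate_profile(gt_flat, oc, 0.15),
                  numeric(1))
  expect_equal(rates, rep(15, 6))
  # inhibited: multiplicative suppression, never negative
  gt_inh <- gt
  gt_inh$polarity <- "inhibited"
  gt_inh$amplitude[] <- 0.8
  expect_equal(rate_profile(gt_inh, 5, 0.15), 5 * (1 - 0.8))
  expect_true(all(rate_profile(gt_inh, 5, seq(-1, 1, 0.01)) >= 0))
})

test_that("thinning sampler is Poisson with the requested intensity", {
  expect_identical(
    sample_inhomogeneous_poisson(function(t) rep(0, length(t)), 0, 10, 0,
                                 seed = 1),
    numeric(0))
  st <- sample_inhomogeneous_poisson(function(t) rep(10, length(t)),
                                     0, 1000, 10, seed = 2)
  # 99% Poisson interval around 10^4
  expect_gt(length(st), qpois(0.005, 1e4))
  expect_lt(length(st), qpois(0.995, 1e4))
  expect_false(is.unsorted(st, strictly = TRUE))
  # inter-spike intervals exponential (KS at alpha = 0.01)
  ks <- suppressWarnings(ks.test(diff(st), "pexp", rate = 10))
  expect_gt(ks$p.value, 0.01)
  # dominating-rate violation is an error
  expect_error(
    sample_inhomogeneous_poisson(function(t) rep(20, length(t)), 0, 10, 10,
                                 seed = 3),
    "rate_max")
})

test_that("generated tuning decays monotonically with chain distance", {
  g <- generate_session(quick_config(n_units = 30, tuning_lambda = 1.5,
                                     seed = 8))
  gt <- g$ground_truth$table
  for (uid in unique(gt$unit_id)) {
    d <- gt[gt$unit_id == uid, ]
    if (!d$responsive[1]) next
    dc <- abs(d$odour_carbon - d$best_odour_carbon)
    expect_true(all(diff(d$amplitude[order(dc)]) <= 1e-12))
    expect_equal(d$odour_carbon[which.max(d$amplitude)],
                 d$best_odour_carbon[1])
  }
})

test_that("baseline firing rates are recovered within Poisson error", {
  # non-responsive units: whole-session rate should match ground truth
  g <- generate_session(quick_config(n_units = 12, p_responsive = 0,
                                     seed = 21))
  span <- g$session$span
  for (u in g$session$units) {
    b <- g$ground_truth$units[[u$unit_id]]$baseline_rate
    n <- length(u$spike_times)
    expect_gte(n, qpois(0.005, b * span))
    expect_lte(n, qpois(0.995, b * span))
  }
})

test_that("synthesised raw traces insert templates and calibrated noise", {
  tr <- toy_trials(c(3, 4), c(5, 15))
  s <- toy_session(list(c(2.0)), tr, span = 3)  # one spike at 2.0 s
  fs <- 30000
  w <- spike_template(fs)
  out <- synthesize_raw_traces(s, channels_per_tetrode = 2, fs = fs,
                               waveform = w, noise_sd = 0, seed = 1)
  s0 <- floor(2.0 * fs) + 1
  expect_equal(out$traces[1, s0:(s0 + length(w) - 1)], w)
  expect_equal(out$traces[2, s0:(s0 + length(w) - 1)], w)
  expect_true(all(out$traces[, 1:(s0 - 1)] == 0))
  # pure unit Gaussian noise: median |x| = qnorm(0.75)
  s_empty <- toy_session(list(numeric(0)), tr, span = 3)
  out2 <- synthesize_raw_traces(s_empty, channels_per_tetrode = 4, fs = fs,
                                waveform = w, noise_sd = 1, seed = 2)
  expect_equal(median(abs(out2$traces)), qnorm(0.75), tolerance = 0.02)
  # seeded determinism
  out3 <- synthesize_raw_traces(s_empty, channels_per_tetrode = 4, fs = fs,
                                waveform = w, noise_sd = 1, seed = 2)
  expect_identical(out2$traces, out3$traces)
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(generator_config(p_responsive = 1.3), "p_responsive")
  expect_error(generator_config(pre_onset_baseline = 1), "pre_onset_baseline")
  expect_error(generator_config(n_trials_per_odour = 1), "n_trials_per_odour")
  expect_error(generator_config(tuning_lambda = -1), "tuning_lambda")
  expect_error(generator_config(odour_duration = 0), "odour_duration")
})

test_that("downstream classification recovers the ground-truth response
           structure at scale", {
  cfg <- genotype_preset("control", n_units = 500, seed = 42)
  g <- generate_session(cfg)
  lab <- classify_responses(g$session)
  lab <- lab[order(lab$unit_id, lab$odour_carbon), ]
  exp_z <- mapply(function(i, oc) {
    expected_mean_window_z(g$ground_truth$units[[i]], oc, cfg)
  }, rep(seq_len(cfg$n_units), each = 6), rep(3:8, times = cfg$n_units))
  exp_lab <- ifelse(exp_z > 1.96, "excited",
                    ifelse(exp_z < -1.96, "inhibited", "none"))
  # pair-fraction recovery within +-0.05 of the model-implied targets
  expect_lt(abs(mean(lab$label == "excited") - mean(exp_lab == "excited")),
            0.05)
  expect_lt(abs(mean(lab$label == "inhibited") -
                  mean(exp_lab == "inhibited")), 0.05)
  # responsive-unit fraction recovery
  obs_units <- tapply(lab$label != "none", lab$unit_id, any)
  exp_units <- tapply(exp_lab != "none",
                      rep(seq_len(cfg$n_units), each = 6), any)
  expect_lt(abs(mean(obs_units) - mean(exp_units)), 0.05)
  # clearly detectable pairs (|expected z| > 3) classified with the right
  # polarity almost always
  clear <- abs(exp_z) > 3
  expect_gt(mean(lab$label[clear] == exp_lab[clear]), 0.9)
})
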