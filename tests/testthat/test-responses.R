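test_that("PSTH averages binned rates across trials", {
  tr <- toy_trials(c(3, 3, 4), c(10, 30, 50))
  # unit 1: 2 spikes in the first 50 ms bin of trial 1 only
  s <- toy_session(list(c(10.01, 0.02 + 10)), tr)
  p1 <- compute_psth(s, 1, 3)
  bin1 <- which(p1$center > 0 & p1$center < 0.05)
  expect_equal(p1$rate[bin1], mean(c(2, 0)) / 0.05)  # 20 Hz
  expect_true(all(p1$rate[-bin1] == 0))
  # single-trial odour: 2 spikes in one bin -> 40 Hz
  s2 <- toy_session(list(c(50.01, 50.02)), tr)
  p2 <- compute_psth(s2, 1, 4)
  expect_equal(p2$rate[p2$center > 0 & p2$center < 0.05], 2 / 0.05)
  # silent unit: all-zero PSTH
  s3 <- toy_session(list(numeric(0)), tr)
  expect_true(all(compute_psth(s3, 1, 3)$rate == 0))
  expect_error(compute_psth(s, 1, 8), "no trials")
})

test_that("z-scored response reproduces the standardisation formula", {
  # one odour, one trial; spikes laid out so baseline bins alternate 0/1
  # counts and odour-window bins hold 2 spikes each
  onset <- 10
  baseline_spikes <- onset + seq(-2.45, -0.55, by = 0.2)  # every 2nd bin
  odour_spikes <- onset + as.vector(outer(c(0.01, 0.06),
                                          seq(0, 0.4, by = 0.1), "+"))
  tr <- toy_trials(3, onset)
  s <- toy_session(list(sort(c(baseline_spikes, odour_spikes))), tr)
  zr <- zscore_response(s, 1, 3)
  # manual recomputation from first principles
  base_counts <- rep(c(1, 0), 10)          # 20 baseline bins of 100 ms
  fr_b <- mean(base_counts / 0.1)
  sd_b <- sd(base_counts / 0.1)
  expect_equal(zr$fr_baseline, fr_b)
  expect_equal(zr$sd_baseline, sd_b)
  expect_equal(zr$mean_window_z, (20 - fr_b) / sd_b)
  expect_equal(zr$label, "excited")
  in_base <- zr$center < -0.5
  expect_equal(zr$z[in_base], (base_counts / 0.1 - fr_b) / sd_b)
})

test_that("constant-rate unit is degenerate and labelled none", {
  onset <- 10
  tr <- toy_trials(3, onset)
  # exactly one spike per 100 ms bin everywhere: zero baseline variance
  s <- toy_session(list(onset + seq(-2.45, 1.95, by = 0.1)), tr)
  zr <- zscore_response(s, 1, 3)
  expect_true(zr$degenerate)
  expect_equal(zr$label, "none")
  expect_true(all(is.na(zr$z)))
})

test_that("classification threshold and sign symmetry behave as specified", {
  # suppressed odour window mirrors the excited case with opposite label
  onset <- 10
  tr <- toy_trials(3, onset)
  baseline_spikes <- onset + sort(c(seq(-2.45, -0.55, by = 0.1),
                                    seq(-2.48, -0.58, by = 0.2)))
  s <- toy_session(list(baseline_spikes), tr)  # nothing in odour window
  zr <- zscore_response(s, 1, 3)
  expect_equal(zr$label, "inhibited")
  expect_lt(zr$mean_window_z, -1.96)
})

test_that("response fractions count units and pairs correctly", {
  lab <- data.frame(
    unit_id = rep(1:2, each = 6), odour_carbon = rep(3:8, 2),
    mean_window_z = 0,
    label = c("excited", rep("none", 11)),
    degenerate = FALSE, genotype = "control", region = "MOB")
  f <- response_fractions(lab)
  expect_equal(f$frac_responsive_units, 0.5)
  expect_equal(f$n_excited, 1)
  expect_equal(f$frac_excited_pairs, 1 / 12)
  lab2 <- lab
  lab2$label <- c(rep("excited", 3), "inhibited", rep("none", 8))
  f2 <- response_fractions(lab2)
  expect_equal(f2$frac_excited_pairs, 3 / 12)
  expect_equal(f2$frac_inhibited_pairs, 1 / 12)
  lab$label <- "none"
  expect_equal(response_fractions(lab)$frac_responsive_units, 0)
  expect_error(response_fractions(lab[0, ]), "empty")
})

test_that("peak features: amplitude, latency and interpolated width", {
  zr <- fake_zresponse(c(0, 1, 3, 1, 0, 0, 0, 0, 0, 0))
  f <- peak_features(zr, "excited")
  expect_equal(f$peak_z, 3)
  expect_equal(f$time_to_peak, 0.25)
  expect_equal(f$peak_width, 0.15)
  # inhibited mirror: same width and latency, negated amplitude
  zr_neg <- fake_zresponse(-c(0, 1, 3, 1, 0, 0, 0, 0, 0, 0))
  f2 <- peak_features(zr_neg, "inhibited")
  expect_equal(f2$peak_z, -3)
  expect_equal(f2$peak_width, f$peak_width)
  expect_equal(f2$time_to_peak, f$time_to_peak)
  # flat trace: features flagged missing
  expect_true(peak_features(fake_zresponse(rep(1, 10)), "excited")$missing)
})

test_that("d-prime follows the RMS-normalised mean difference", {
  # means 10 and 6, both sds exactly 2
  r <- pairwise_dprime(c(8, 10, 12), c(4, 6, 8))
  expect_equal(r$sigma_rms, 2)
  expect_equal(r$dprime, 2)
  # symmetry
  r2 <- pairwise_dprime(c(4, 6, 8), c(8, 10, 12))
  expect_equal(r2$dprime, r$dprime)
  # identical counts
  expect_equal(pairwise_dprime(c(5, 5, 5), c(5, 5, 5))$dprime, 0)
  # zero variance, different means: flagged infinite
  ri <- pairwise_dprime(c(5, 5), c(7, 7))
  expect_true(ri$infinite)
  # invariance: shared additive shift and shared positive rescaling
  a <- c(3, 7, 5, 9); b <- c(1, 2, 4, 2)
  d0 <- pairwise_dprime(a, b)$dprime
  expect_equal(pairwise_dprime(a + 11, b + 11)$dprime, d0)
  expect_equal(pairwise_dprime(a * 2.5, b * 2.5)$dprime, d0)
  expect_error(pairwise_dprime(1, c(1, 2)), ">= 2 trials")
})

test_that("feature comparison gates between t and Mann-Whitney", {
  r <- compare_feature_distributions(c(1, 2, 3), c(4, 5, 6),
                                     test = "mann_whitney")
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 0.1)
  set.seed(31)
  x <- rnorm(40); y <- rnorm(40, 0.5)
  rt <- compare_feature_distributions(x, y, test = "auto")
  expect_equal(rt$test, "t_test")
  expect_equal(rt$p, t.test(x, y)$p.value)
  xs <- exp(rnorm(40, sd = 2))  # clearly non-normal
  rg <- compare_feature_distributions(xs, y, test = "auto")
  expect_equal(rg$test, "mann_whitney")
  expect_error(compare_feature_distributions(rep(1, 5), rep(1, 5)),
               "degenerate")
})

test_that("z labelling has a low false-positive rate under a stationary
           Poisson null", {
  g <- generate_session(genotype_preset("control", n_units = 200,
                                        p_responsive = 0, seed = 77))
  lab <- classify_responses(g$session)
  expect_gte(nrow(lab), 1000)
  expect_gte(mean(lab$label == "none"), 0.95)
})

test_that("recovered peak amplitude grows with generated gain", {
  med_peak <- vapply(c(1, 2.5, 5), function(amp) {
    g <- generate_session(quick_config(
      n_units = 25, n_trials_per_odour = 10, p_responsive = 1,
      p_inhibited_given_responsive = 0, amp_mean = amp, amp_sd = 1e-6,
      tuning_lambda = Inf, seed = 55))
    peaks <- vapply(g$session$units, function(u) {
      zr <- zscore_response(g$session, u$unit_id, 3)
      if (zr$degenerate) return(NA_real_)
      peak_features(zr, "excited")$peak_z
    }, numeric(1))
    median(peaks, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(med_peak) > 0))
})

test_that("per-unit d-prime summaries separate tuned from untuned
           populations", {
  g_tuned <- generate_session(quick_config(
    n_units = 20, n_trials_per_odour = 10, p_responsive = 1,
    p_inhibited_given_responsive = 0, amp_mean = 4, tuning_lambda = 1,
    seed = 60))
  g_null <- generate_session(quick_config(
    n_units = 20, n_trials_per_odour = 10, p_responsive = 0, seed = 61))
  d_tuned <- unit_dprimes(g_tuned$session)
  d_null <- unit_dprimes(g_null$session)
  expect_equal(nrow(d_tuned$pairs), 20 * choose(6, 2))
  expect_gt(median(d_tuned$per_unit$max_dprime),
            median(d_null$per_unit$max_dprime))
})
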