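#' Configuration for the synthetic session generator
#'
#' Builds the full parameter set for [generate_session()]. The defaults
#' mirror the experimental design the pipeline targets: six monomolecular
#' aldehydes identified by carbon chain length 3--8, 19 trials per odour,
#' 500 ms odour presentation, and a pre-onset epoch long enough to contain
#' the -2.5 to -0.5 s baseline window used downstream.
#'
#' Response heterogeneity across the population is controlled by a small
#' set of distributions: baseline firing rates are log-normal; a unit is
#' odour-responsive with probability `p_responsive` and, if responsive,
#' inhibited (rather than excited) with probability
#' `p_inhibited_given_responsive`. Excited units multiply their baseline by
#' `1 + A_o * g(t)` where `g` is a peak-normalised response kernel and the
#' per-odour gain decays with chemical distance from the unit's best odour,
#' `A_o = A * exp(-|c_o - c_best| / tuning_lambda)`. `tuning_lambda = Inf`
#' gives flat (untuned) responses. Inhibited units use multiplicative
#' suppression `1 - s_o * g(t)` with `s_o` in `[0, 1)` so rates never go
#' negative.
#'
#' @param n_units number of single units to simulate.
#' @param region recording region, `"MOB"` or `"AON"`.
#' @param genotype `"control"` or `"mutant"` (metadata label only; use
#'   [genotype_preset()] for parameter sets that differ by genotype).
#' @param n_trials_per_odour trials per odour (>= 2).
#' @param odour_carbons integer carbon chain lengths identifying the odours.
#' @param odour_duration stimulus duration, seconds.
#' @param pre_onset_baseline seconds of recording before each odour onset;
#'   must be >= 2.5 so the analysis baseline window is in-session.
#' @param inter_trial_interval seconds per trial epoch (onset-to-onset).
#' @param baseline_rate_log_mean,baseline_rate_log_sd log-scale mean/sd of
#'   the log-normal baseline firing-rate distribution (Hz).
#' @param p_responsive probability a unit responds to the odour set.
#' @param p_inhibited_given_responsive probability a responsive unit is
#'   inhibited rather than excited.
#' @param amp_mean,amp_sd mean/sd of the dimensionless multiplicative
#'   response gain `A` (truncated below at 0.1).
#' @param latency_mean,latency_sd mean/sd of the kernel peak latency (s).
#' @param kernel_width_mean,kernel_width_sd mean/sd of the kernel full width
#'   at half maximum (s).
#' @param tuning_lambda chemical-similarity decay constant in carbon-chain
#'   units; `Inf` means flat tuning.
#' @param seed integer seed; the generator is fully deterministic given the
#'   configuration and seed.
#'
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(n_units = 50L,
                             region = c("MOB", "AON"),
                             genotype = c("control", "mutant"),
                             n_trials_per_odour = 19L,
                             odour_carbons = 3:8,
                             odour_duration = 0.5,
                             pre_onset_baseline = 5.0,
                             inter_trial_interval = 10.0,
                             baseline_rate_log_mean = log(10),
                             baseline_rate_log_sd = 0.6,
                             p_responsive = 0.5,
                             p_inhibited_given_responsive = 0.4,
                             amp_mean = 3.0,
                             amp_sd = 1.0,
                             latency_mean = 0.12,
                             latency_sd = 0.03,
                             kernel_width_mean = 0.35,
                             kernel_width_sd = 0.08,
                             tuning_lambda = 1.2,
                             seed = 1L) {
  region <- match.arg(region)
  genotype <- match.arg(genotype)
  cfg <- list(
    n_units = as.integer(n_units), region = region, genotype = genotype,
    n_trials_per_odour = as.integer(n_trials_per_odour),
    odour_carbons = as.integer(sort(odour_carbons)),
    odour_duration = odour_duration,
    pre_onset_baseline = pre_onset_baseline,
    inter_trial_interval = inter_trial_interval,
    baseline_rate_log_mean = baseline_rate_log_mean,
    baseline_rate_log_sd = baseline_rate_log_sd,
    p_responsive = p_responsive,
    p_inhibited_given_responsive = p_inhibited_given_responsive,
    amp_mean = amp_mean, amp_sd = amp_sd,
    latency_mean = latency_mean, latency_sd = latency_sd,
    kernel_width_mean = kernel_width_mean, kernel_width_sd = kernel_width_sd,
    tuning_lambda = tuning_lambda,
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid generator config: field '", field, "' ", msg,
                  call. = FALSE)
  }
  chk(cfg$n_units >= 1, "n_units", "must be >= 1")
  chk(cfg$n_trials_per_odour >= 2, "n_trials_per_odour", "must be >= 2")
  chk(length(cfg$odour_carbons) >= 2 && !anyDuplicated(cfg$odour_carbons),
      "odour_carbons", "must be >= 2 distinct integers")
  chk(cfg$odour_duration > 0, "odour_duration", "must be > 0")
  chk(cfg$pre_onset_baseline >= 2.5, "pre_onset_baseline",
      "must be >= 2.5 s to cover the analysis baseline window")
  chk(cfg$inter_trial_interval >
        cfg$pre_onset_baseline + cfg$odour_duration,
      "inter_trial_interval", "must exceed pre_onset_baseline + odour_duration")
  for (p in c("p_responsive", "p_inhibited_given_responsive")) {
    chk(cfg[[p]] >= 0 && cfg[[p]] <= 1, p, "must lie in [0, 1]")
  }
  chk(cfg$tuning_lambda > 0, "tuning_lambda", "must be > 0 (Inf = flat)")
  chk(cfg$amp_mean > 0, "amp_mean", "must be > 0")
  chk(cfg$kernel_width_mean > 0, "kernel_width_mean", "must be > 0")
  chk(cfg$latency_mean > 0, "latency_mean", "must be > 0")
  invisible(cfg)
}

#' Genotype preset configurations
#'
#' Returns a [generator_config()] whose response statistics differ by
#' genotype in the directions the pipeline is designed to detect: the
#' mutant preset has a lower fraction of responsive units, fewer inhibited
#' responses, smaller response gains, slower and broader response kernels,
#' and flat chemical tuning (`tuning_lambda = Inf`); the control preset has
#' finite tuning decay. All magnitudes are calibration constants of the
#' simulator, not measured quantities.
#'
#' @param genotype `"control"` or `"mutant"`.
#' @param region `"MOB"` or `"AON"`.
#' @param n_units number of units.
#' @param seed integer seed.
#' @param ... further overrides passed to [generator_config()].
#' @return A `"generator_config"`.
#' @export
genotype_preset <- function(genotype = c("control", "mutant"),
                            region = c("MOB", "AON"),
                            n_units = 100L, seed = 1L, ...) {
  genotype <- match.arg(genotype)
  region <- match.arg(region)
  # AON units fire more sparsely than mitral/tufted cells in the bulb
  log_mean <- if (region == "AON") log(4) else log(10)
  preset <- if (genotype == "control") {
    list(p_responsive = 0.5, p_inhibited_given_responsive = 0.4,
         amp_mean = 3.0, amp_sd = 1.0,
         latency_mean = 0.12, latency_sd = 0.03,
         kernel_width_mean = 0.35, kernel_width_sd = 0.08,
         tuning_lambda = 1.2)
  } else {
    list(p_responsive = 0.25, p_inhibited_given_responsive = 0.2,
         amp_mean = 1.0, amp_sd = 0.4,
         latency_mean = 0.2, latency_sd = 0.05,
         kernel_width_mean = 0.5, kernel_width_sd = 0.1,
         tuning_lambda = Inf)
  }
  args <- utils::modifyList(
    c(list(n_units = n_units, region = region, genotype = genotype,
           baseline_rate_log_mean = log_mean, seed = seed), preset),
    list(...))
  do.call(generator_config, args)
}

# Peak-normalised response kernel: Gaussian bump centred at the latency,
# sd = FWHM / (2*sqrt(2*log(2))), supported on [0, latency + 4 sd).
response_kernel <- function(t, latency, width) {
  sdev <- width / (2 * sqrt(2 * log(2)))
  g <- exp(-(t - latency)^2 / (2 * sdev^2))
  g[t < 0 | t >= latency + 4 * sdev] <- 0
  g
}

kernel_support_end <- function(latency, width) {
  latency + 4 * width / (2 * sqrt(2 * log(2)))
}

#' Instantaneous firing rate of a simulated unit
#'
#' Evaluates the rate model for one unit at times `t` relative to odour
#' onset. Excited units: `b * (1 + A_o * g(t))`; inhibited units:
#' `b * (1 - s_o * g(t))` with `s_o` in `[0, 1)`; non-responsive units stay
#' at baseline. Rates are clamped at zero.
#'
#' @param gt a single unit's ground truth, as returned in the
#'   `units` element of [generate_session()]'s ground truth.
#' @param odour_carbon integer carbon number of the presented odour.
#' @param t numeric vector of times (s) relative to odour onset.
#' @return Numeric vector of rates (Hz).
#' @export
rate_profile <- function(gt, odour_carbon, t) {
  b <- gt$baseline_rate
  if (!gt$responsive || gt$polarity == "none") return(rep(b, length(t)))
  gain <- gt$amplitude[[as.character(odour_carbon)]]
  g <- response_kernel(t, gt$latency, gt$width)
  r <- if (gt$polarity == "excited") b * (1 + gain * g) else b * (1 - gain * g)
  pmax(r, 0)
}

#' Sample an inhomogeneous Poisson process by thinning
#'
#' Draws candidate events from a homogeneous Poisson process at rate
#' `rate_max` on `[t0, t1)` and accepts each candidate with probability
#' `rate_fn(t) / rate_max`.
#'
#' @param rate_fn vectorised intensity function of time (Hz); must not
#'   exceed `rate_max` anywhere on the interval.
#' @param t0,t1 interval bounds (s), `t1 > t0`.
#' @param rate_max dominating rate (Hz).
#' @param seed optional integer seed.
#' @return Strictly increasing event times in `[t0, t1)`.
#' @export
sample_inhomogeneous_poisson <- function(rate_fn, t0, t1, rate_max,
                                         seed = NULL) {
  stopifnot(t1 > t0, rate_max >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (rate_max == 0) return(numeric(0))
  n <- stats::rpois(1, rate_max * (t1 - t0))
  if (n == 0) return(numeric(0))
  cand <- sort(stats::runif(n, t0, t1))
  r <- rate_fn(cand)
  if (any(r > rate_max * (1 + 1e-9))) {
    stop("rate_fn exceeds rate_max at a probed point (max ",
         format(max(r)), " > ", format(rate_max), ")", call. = FALSE)
  }
  keep <- stats::runif(n) < r / rate_max
  cand[keep]
}

#' Generate a synthetic recording session
#'
#' Simulates one session of sorted single units responding to randomly
#' ordered odour presentations, together with the generative ground truth
#' of every unit (for parameter-recovery tests). Trial epochs are laid out
#' back-to-back, `inter_trial_interval` seconds each, with the odour onset
#' `pre_onset_baseline` seconds into each epoch. Spike trains are drawn
#' from the [rate_profile()] intensity by thinning
#' ([sample_inhomogeneous_poisson()]). Deterministic given config + seed.
#'
#' @param config a [generator_config()].
#' @return A list with elements `session` (class `"recording_session"`:
#'   `session_id`, `genotype`, `region`, `span`, `units` -- a list of
#'   `(unit_id, tetrode_id, spike_times)` -- and `trials`, a data frame of
#'   `(trial_id, odour_carbon, onset_s, offset_s)`) and `ground_truth`
#'   (list with per-unit parameter lists in `units` and a tidy per
#'   unit-odour data frame in `table`).
#' @export
generate_session <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  carbons <- config$odour_carbons
  n_trials <- config$n_trials_per_odour * length(carbons)
  iti <- config$inter_trial_interval
  span <- n_trials * iti

  odour_seq <- sample(rep(carbons, each = config$n_trials_per_odour))
  onsets <- (seq_len(n_trials) - 1) * iti + config$pre_onset_baseline
  trials <- data.frame(
    trial_id = seq_len(n_trials),
    odour_carbon = odour_seq,
    onset_s = onsets,
    offset_s = onsets + config$odour_duration
  )

  units <- vector("list", config$n_units)
  gt_units <- vector("list", config$n_units)
  for (i in seq_len(config$n_units)) {
    b <- stats::rlnorm(1, config$baseline_rate_log_mean,
                       config$baseline_rate_log_sd)
    responsive <- stats::runif(1) < config$p_responsive
    polarity <- "none"
    amp <- stats::setNames(rep(0, length(carbons)), carbons)
    best <- NA_integer_
    latency <- max(0.02, stats::rnorm(1, config$latency_mean,
                                      config$latency_sd))
    width <- max(0.05, stats::rnorm(1, config$kernel_width_mean,
                                    config$kernel_width_sd))
    if (responsive) {
      inhibited <- stats::runif(1) < config$p_inhibited_given_responsive
      polarity <- if (inhibited) "inhibited" else "excited"
      best <- sample(carbons, 1)
      a <- max(0.1, stats::rnorm(1, config$amp_mean, config$amp_sd))
      decay <- exp(-abs(carbons - best) / config$tuning_lambda)
      if (inhibited) {
        # map the gain into [0, 1) so suppressed rates stay non-negative
        amp[] <- (a / (1 + a)) * decay
      } else {
        amp[] <- a * decay
      }
    }
    gt <- list(unit_id = i, baseline_rate = b, responsive = responsive,
               polarity = polarity, best_odour_carbon = best,
               amplitude = amp, latency = latency, width = width)
    gt_units[[i]] <- gt

    rate_max <- if (polarity == "excited") b * (1 + max(amp)) else b
    rate_fn <- function(tt) session_rate(gt, trials, config, tt)
    st <- sample_inhomogeneous_poisson(rate_fn, 0, span, rate_max)
    units[[i]] <- list(unit_id = i, tetrode_id = ((i - 1L) %/% 4L) + 1L,
                       spike_times = st)
  }

  session <- structure(list(
    session_id = sprintf("sim_%s_%s_seed%d", config$genotype, config$region,
                         config$seed),
    genotype = config$genotype, region = config$region, span = span,
    units = units, trials = trials
  ), class = "recording_session")

  gt_table <- do.call(rbind, lapply(gt_units, function(g) {
    data.frame(unit_id = g$unit_id, odour_carbon = carbons,
               baseline_rate = g$baseline_rate, responsive = g$responsive,
               polarity = if (g$responsive) g$polarity else "none",
               best_odour_carbon = g$best_odour_carbon,
               amplitude = unname(g$amplitude),
               latency = g$latency, width = g$width)
  }))

  list(session = session,
       ground_truth = list(units = gt_units, table = gt_table))
}

# Session-wide intensity for one unit: baseline everywhere, modulated
# within the response-kernel support of each trial. Trial epochs are
# regular, so the epoch index is floor(t / iti).
session_rate <- function(gt, trials, config, t) {
  b <- gt$baseline_rate
  r <- rep(b, length(t))
  if (!gt$responsive || gt$polarity == "none") return(r)
  iti <- config$inter_trial_interval
  idx <- pmin(floor(t / iti) + 1L, nrow(trials))
  t_rel <- t - trials$onset_s[idx]
  sup <- kernel_support_end(gt$latency, gt$width)
  in_resp <- t_rel >= 0 & t_rel < sup
  if (!any(in_resp)) return(r)
  gain <- gt$amplitude[as.character(trials$odour_carbon[idx[in_resp]])]
  g <- response_kernel(t_rel[in_resp], gt$latency, gt$width)
  if (gt$polarity == "excited") {
    r[in_resp] <- b * (1 + gain * g)
  } else {
    r[in_resp] <- pmax(b * (1 - gain * g), 0)
  }
  r
}

#' Default extracellular spike waveform template
#'
#' Biphasic (negative-leading) template sampled at `fs`, used when
#' synthesising raw voltage traces.
#'
#' @param fs sampling rate (Hz).
#' @param amplitude peak (negative lobe) amplitude, microvolts.
#' @param duration template duration (s), at most 3 ms.
#' @return Numeric vector of template samples (microvolts).
#' @export
spike_template <- function(fs = 30000, amplitude = 60, duration = 0.002) {
  stopifnot(duration <= 0.003)
  t <- seq(0, duration, by = 1 / fs)
  w <- -amplitude * exp(-(t - 3e-4)^2 / (2 * (1e-4)^2)) +
    0.3 * amplitude * exp(-(t - 9e-4)^2 / (2 * (2.5e-4)^2))
  w
}

#' Synthesise multichannel raw voltage traces from a session
#'
#' Inserts a spike waveform template at every spike time of every unit on
#' all channels of the unit's tetrode and adds white Gaussian noise.
#' Overlapping insertions sum. Intended as a fixture substrate for the
#' spike-detection stage; use short sessions (the trace covers the whole
#' session span at `fs`).
#'
#' @param session a `"recording_session"`.
#' @param channels_per_tetrode channels per tetrode (default 4).
#' @param fs sampling rate (Hz), >= 10 kHz.
#' @param waveform template vector (see [spike_template()]); duration at
#'   most 3 ms.
#' @param noise_sd Gaussian noise standard deviation (microvolts).
#' @param seed optional integer seed for the noise.
#' @return List with `traces` (channels x samples matrix, microvolts),
#'   `fs`, and `channel_map` (data frame channel -> tetrode).
#' @export
synthesize_raw_traces <- function(session, channels_per_tetrode = 4L,
                                  fs = 30000, waveform = spike_template(fs),
                                  noise_sd = 5, seed = NULL) {
  stopifnot(fs >= 10000, length(waveform) / fs <= 0.003 + 1e-9)
  if (!is.null(seed)) set.seed(seed)
  tetrodes <- sort(unique(vapply(session$units, `[[`, 1L, "tetrode_id")))
  n_chan <- length(tetrodes) * channels_per_tetrode
  n_samp <- ceiling(session$span * fs) + length(waveform)
  traces <- matrix(stats::rnorm(n_chan * n_samp, 0, noise_sd),
                   nrow = n_chan, ncol = n_samp)
  channel_map <- data.frame(
    channel = seq_len(n_chan),
    tetrode = rep(tetrodes, each = channels_per_tetrode)
  )
  lw <- length(waveform)
  for (u in session$units) {
    chans <- channel_map$channel[channel_map$tetrode == u$tetrode_id]
    for (st in u$spike_times) {
      s0 <- floor(st * fs) + 1L
      idx <- s0:(s0 + lw - 1L)
      traces[chans, idx] <- traces[chans, idx] +
        matrix(waveform, nrow = length(chans), ncol = lw, byrow = TRUE)
    }
  }
  list(traces = traces, fs = fs, channel_map = channel_map)
}

#' Model-implied mean-window z-score of a unit-odour pair
#'
#' Computes, from a unit's generative ground truth, the expected mean
#' z-score over the odour-window bins that the downstream classifier
#' measures: the trial-averaged rate change in each bin divided by the
#' expected baseline standard deviation of the trial-averaged binned rate
#' (Poisson counts: `sqrt(b / (z_bin * n_trials))`). Used for
#' parameter-recovery tests of the classification stage.
#'
#' @param gt a single unit's ground truth (from [generate_session()]).
#' @param odour_carbon odour (carbon chain length).
#' @param config the [generator_config()] used for generation.
#' @param windows an [analysis_windows()].
#' @return Expected mean-window z (0 for non-responsive units).
#' @export
expected_mean_window_z <- function(gt, odour_carbon,
                                   config, windows = analysis_windows()) {
  b <- gt$baseline_rate
  sd_b <- sqrt(b / (windows$z_bin * config$n_trials_per_odour))
  if (!gt$responsive || gt$polarity == "none" || sd_b == 0) return(0)
  gain <- gt$amplitude[[as.character(odour_carbon)]]
  edges <- seq(windows$odour_window[1], windows$odour_window[2],
               by = windows$z_bin)
  dz <- vapply(seq_len(length(edges) - 1), function(i) {
    g_bar <- stats::integrate(response_kernel, edges[i], edges[i + 1],
                              latency = gt$latency,
                              width = gt$width)$value / windows$z_bin
    sgn <- if (gt$polarity == "excited") 1 else -1
    sgn * b * gain * g_bar / sd_b
  }, numeric(1))
  mean(dz)
}
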