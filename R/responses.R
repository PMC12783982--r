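#' Analysis window settings
#'
#' Time windows and thresholds for single-unit response analysis. All
#' windows are half-open `[a, b)` and expressed relative to odour onset;
#' bin timestamps are bin centres. The classification threshold defaults to
#' the two-sided 95% standard-normal critical value.
#'
#' @param psth_bin PSTH bin width (s), default 0.05.
#' @param z_bin z-score trace bin width (s), default 0.1.
#' @param baseline_window `[a, b)` (s) defining the pre-odour baseline,
#'   default `c(-2.5, -0.5)`.
#' @param odour_window `[a, b)` (s) of the stimulus, default `c(0, 0.5)`.
#' @param feature_window `[a, b)` (s) searched for response peaks, default
#'   `c(0, 1)` (responses can outlast the 500 ms stimulus).
#' @param span full analysis span `[a, b)` (s) around onset.
#' @param z_thr classification threshold on the mean odour-window z-score,
#'   default `round(qnorm(0.975), 2)` = 1.96.
#' @return List of class `"analysis_windows"`.
#' @export
analysis_windows <- function(psth_bin = 0.05, z_bin = 0.1,
                             baseline_window = c(-2.5, -0.5),
                             odour_window = c(0, 0.5),
                             feature_window = c(0, 1),
                             span = c(-2.5, 2.0),
                             z_thr = round(stats::qnorm(0.975), 2)) {
  stopifnot(psth_bin > 0, z_bin > 0, z_thr > 0,
            baseline_window[1] < baseline_window[2],
            baseline_window[2] <= odour_window[1],
            odour_window[1] < odour_window[2],
            span[1] <= baseline_window[1], span[2] >= odour_window[2])
  structure(list(psth_bin = psth_bin, z_bin = z_bin,
                 baseline_window = baseline_window,
                 odour_window = odour_window,
                 feature_window = feature_window,
                 span = span, z_thr = z_thr),
            class = "analysis_windows")
}

unit_by_id <- function(session, unit_id) {
  for (u in session$units) if (u$unit_id == unit_id) return(u)
  stop("no unit with id ", unit_id, " in session ", session$session_id,
       call. = FALSE)
}

# Trial-by-bin spike count matrix for one unit and odour, bins tiling
# [span[1], span[2]) half-open, aligned to odour onset.
trial_bin_counts <- function(session, unit_id, odour_carbon, bin, span) {
  u <- unit_by_id(session, unit_id)
  onsets <- session$trials$onset_s[session$trials$odour_carbon == odour_carbon]
  if (length(onsets) == 0) {
    stop("session ", session$session_id, " has no trials of odour carbon ",
         odour_carbon, call. = FALSE)
  }
  edges <- seq(span[1], span[2], by = bin)
  n_bins <- length(edges) - 1L
  counts <- matrix(0L, nrow = length(onsets), ncol = n_bins)
  for (i in seq_along(onsets)) {
    rel <- u$spike_times - onsets[i]
    rel <- rel[rel >= span[1] & rel < span[2]]
    if (length(rel)) {
      idx <- findInterval(rel, edges, rightmost.closed = FALSE)
      tab <- tabulate(idx, nbins = n_bins)
      counts[i, ] <- tab
    }
  }
  list(counts = counts, centers = edges[-length(edges)] + bin / 2)
}

#' Peri-stimulus time histogram
#'
#' Trial-averaged firing rate of one unit around the onsets of one odour,
#' in half-open bins aligned to odour onset.
#'
#' @param session a `"recording_session"`.
#' @param unit_id unit identifier.
#' @param odour_carbon odour (carbon chain length).
#' @param bin bin width (s), default 0.05.
#' @param span `[a, b)` analysis span (s) relative to onset.
#' @return Data frame with bin `center` (s) and `rate` (Hz).
#' @export
compute_psth <- function(session, unit_id, odour_carbon, bin = 0.05,
                         span = c(-2.5, 2.0)) {
  tb <- trial_bin_counts(session, unit_id, odour_carbon, bin, span)
  data.frame(center = tb$centers, rate = colMeans(tb$counts) / bin)
}

#' z-scored odour response of a unit
#'
#' Averages responses to one odour across trials, then standardises the
#' binned rate trace by the mean and standard deviation of the baseline
#' window: `z_t = (FR_t - FR_baseline) / sigma_baseline`. The unit-odour
#' pair is labelled `excited` if the mean z over the odour-window bins
#' exceeds `+z_thr`, `inhibited` below `-z_thr`, otherwise `none`. Pairs
#' with zero baseline variability are flagged `degenerate` and carry label
#' `none` with `NA` z-scores.
#'
#' @param session a `"recording_session"`.
#' @param unit_id unit identifier.
#' @param odour_carbon odour (carbon chain length).
#' @param windows an [analysis_windows()].
#' @return List of class `"z_response"`: `unit_id`, `odour_carbon`,
#'   `center` (bin centres, s), `rate` (Hz), `z` per bin, `fr_baseline`,
#'   `sd_baseline`, `mean_window_z`, `label`, `degenerate`.
#' @export
zscore_response <- function(session, unit_id, odour_carbon,
                            windows = analysis_windows()) {
  tb <- trial_bin_counts(session, unit_id, odour_carbon, windows$z_bin,
                         windows$span)
  rate <- colMeans(tb$counts) / windows$z_bin
  centers <- tb$centers
  base <- centers >= windows$baseline_window[1] &
    centers < windows$baseline_window[2]
  if (sum(base) < 2) stop("fewer than 2 baseline bins", call. = FALSE)
  fr_b <- mean(rate[base])
  sd_b <- stats::sd(rate[base])
  degenerate <- sd_b == 0
  z <- if (degenerate) rep(NA_real_, length(rate)) else (rate - fr_b) / sd_b
  odw <- centers >= windows$odour_window[1] &
    centers < windows$odour_window[2]
  mwz <- if (degenerate) NA_real_ else mean(z[odw])
  label <- if (degenerate || is.na(mwz)) "none"
  else if (mwz > windows$z_thr) "excited"
  else if (mwz < -windows$z_thr) "inhibited"
  else "none"
  structure(list(unit_id = unit_id, odour_carbon = odour_carbon,
                 center = centers, rate = rate, z = z,
                 fr_baseline = fr_b, sd_baseline = sd_b,
                 mean_window_z = mwz, label = label,
                 degenerate = degenerate),
            class = "z_response")
}

#' z-score classification for every unit-odour pair of a session
#'
#' @param session a `"recording_session"`.
#' @param windows an [analysis_windows()].
#' @return Data frame with one row per unit-odour pair: `unit_id`,
#'   `odour_carbon`, `mean_window_z`, `label`, `degenerate`, plus session
#'   `genotype` and `region`.
#' @export
classify_responses <- function(session, windows = analysis_windows()) {
  carbons <- sort(unique(session$trials$odour_carbon))
  rows <- list()
  for (u in session$units) {
    for (oc in carbons) {
      zr <- zscore_response(session, u$unit_id, oc, windows)
      rows[[length(rows) + 1L]] <- data.frame(
        unit_id = u$unit_id, odour_carbon = oc,
        mean_window_z = zr$mean_window_z, label = zr$label,
        degenerate = zr$degenerate,
        genotype = session$genotype, region = session$region
      )
    }
  }
  do.call(rbind, rows)
}

#' Summarise response fractions
#'
#' Fraction of units responsive (excited or inhibited) to at least one
#' odour, and counts/fractions of excited and inhibited unit-odour pairs,
#' per genotype and region.
#'
#' @param labels data frame as returned by [classify_responses()] (rows
#'   from several sessions may be concatenated; unit ids must be unique
#'   across sessions or prefixed by session).
#' @return Data frame with one row per genotype x region.
#' @export
response_fractions <- function(labels) {
  if (is.null(labels) || nrow(labels) == 0) {
    stop("empty label table", call. = FALSE)
  }
  sp <- split(labels, list(labels$genotype, labels$region), drop = TRUE)
  out <- lapply(sp, function(d) {
    per_unit <- tapply(d$label != "none", d$unit_id, any)
    n_pairs <- nrow(d)
    data.frame(genotype = d$genotype[1], region = d$region[1],
               n_units = length(per_unit),
               frac_responsive_units = mean(per_unit),
               n_pairs = n_pairs,
               n_excited = sum(d$label == "excited"),
               n_inhibited = sum(d$label == "inhibited"),
               frac_excited_pairs = sum(d$label == "excited") / n_pairs,
               frac_inhibited_pairs = sum(d$label == "inhibited") / n_pairs)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Peak features of a z-scored response
#'
#' Amplitude, width and latency of the response peak in the z-scored
#' trace. For inhibited responses the negated trace is analysed and the
#' amplitude is reported with its original (negative) sign. The peak is the
#' largest local maximum inside the feature window; its width is measured
#' at half prominence with linear interpolation between bin centres
#' (clipped at the window edges if the trace never falls below the half
#' level); the latency is the peak bin centre.
#'
#' @param zresp a `"z_response"`.
#' @param polarity `"excited"` or `"inhibited"`; should match the label.
#' @param feature_window `[a, b)` search interval (s) relative to onset.
#' @return List `peak_z`, `peak_width`, `time_to_peak`, `missing` (TRUE
#'   when no local maximum exists in the window).
#' @export
peak_features <- function(zresp, polarity = c("excited", "inhibited"),
                          feature_window = c(0, 1)) {
  polarity <- match.arg(polarity)
  in_win <- zresp$center >= feature_window[1] &
    zresp$center < feature_window[2]
  z <- zresp$z[in_win]
  tt <- zresp$center[in_win]
  if (polarity == "inhibited") z <- -z
  miss <- list(peak_z = NA_real_, peak_width = NA_real_,
               time_to_peak = NA_real_, missing = TRUE)
  if (length(z) < 3 || anyNA(z)) return(miss)

  # interior local maxima (plateaus excluded by strict inequality on one side)
  cand <- which(diff(sign(diff(z))) < 0) + 1L
  if (length(cand) == 0) return(miss)
  pk <- cand[which.max(z[cand])]
  peak <- z[pk]
  left_base <- min(z[1:pk])
  right_base <- min(z[pk:length(z)])
  prominence <- peak - max(left_base, right_base)
  half <- peak - prominence / 2

  interp_cross <- function(i_hi, i_lo) {
    # linear interpolation of the time where z crosses `half`
    tt[i_hi] + (tt[i_lo] - tt[i_hi]) * (z[i_hi] - half) / (z[i_hi] - z[i_lo])
  }
  t_left <- tt[1]
  for (i in pk:1) {
    if (z[i] < half) {
      t_left <- interp_cross(i + 1L, i)
      break
    }
  }
  t_right <- tt[length(tt)]
  for (i in pk:length(z)) {
    if (z[i] < half) {
      t_right <- interp_cross(i - 1L, i)
      break
    }
  }
  sign_out <- if (polarity == "inhibited") -1 else 1
  list(peak_z = sign_out * peak, peak_width = t_right - t_left,
       time_to_peak = tt[pk], missing = FALSE)
}

#' Pairwise discriminability index d'
#'
#' `d' = |mu_A - mu_B| / sigma_RMS` where the means are odour-window spike
#' counts averaged across trials and `sigma_RMS = sqrt((sd_A^2 + sd_B^2)/2)`
#' is the root-mean-square of the per-odour count standard deviations.
#' Identical constant counts give d' = 0; distinct constant counts are
#' flagged infinite (and should be excluded from distribution summaries).
#'
#' @param counts_a,counts_b per-trial spike counts for the two odours
#'   (>= 2 trials each).
#' @return List `mu_a`, `mu_b`, `sigma_rms`, `dprime`, `infinite`.
#' @export
pairwise_dprime <- function(counts_a, counts_b) {
  if (length(counts_a) < 2 || length(counts_b) < 2) {
    stop("d' needs >= 2 trials per odour", call. = FALSE)
  }
  mu_a <- mean(counts_a)
  mu_b <- mean(counts_b)
  s_rms <- sqrt((stats::sd(counts_a)^2 + stats::sd(counts_b)^2) / 2)
  if (s_rms == 0) {
    if (mu_a == mu_b) {
      return(list(mu_a = mu_a, mu_b = mu_b, sigma_rms = 0, dprime = 0,
                  infinite = FALSE))
    }
    return(list(mu_a = mu_a, mu_b = mu_b, sigma_rms = 0, dprime = Inf,
                infinite = TRUE))
  }
  list(mu_a = mu_a, mu_b = mu_b, sigma_rms = s_rms,
       dprime = abs(mu_a - mu_b) / s_rms, infinite = FALSE)
}

#' Per-unit d' over all odour pairs
#'
#' Computes d' for every odour pair of every unit from odour-window spike
#' counts and summarises the mean and maximum d' per unit (infinite pairs
#' excluded from the summaries).
#'
#' @param session a `"recording_session"`.
#' @param windows an [analysis_windows()].
#' @return List with `pairs` (one row per unit and odour pair) and
#'   `per_unit` (mean and max d' per unit).
#' @export
unit_dprimes <- function(session, windows = analysis_windows()) {
  carbons <- sort(unique(session$trials$odour_carbon))
  counts <- odour_window_counts(session, windows)
  rows <- list()
  for (u in session$units) {
    uid <- u$unit_id
    for (i in seq_along(carbons)) {
      for (j in seq_along(carbons)) {
        if (j <= i) next
        dp <- pairwise_dprime(counts[[as.character(carbons[i])]][, as.character(uid)],
                              counts[[as.character(carbons[j])]][, as.character(uid)])
        rows[[length(rows) + 1L]] <- data.frame(
          unit_id = uid, carbon_a = carbons[i], carbon_b = carbons[j],
          mu_a = dp$mu_a, mu_b = dp$mu_b, sigma_rms = dp$sigma_rms,
          dprime = dp$dprime, infinite = dp$infinite)
      }
    }
  }
  pairs <- do.call(rbind, rows)
  ok <- !pairs$infinite
  per_unit <- do.call(rbind, lapply(split(pairs[ok, ], pairs$unit_id[ok]),
    function(d) data.frame(unit_id = d$unit_id[1],
                           mean_dprime = mean(d$dprime),
                           max_dprime = max(d$dprime))))
  rownames(per_unit) <- NULL
  list(pairs = pairs, per_unit = per_unit)
}

# Per-odour trial x unit spike-count matrices in the odour window.
odour_window_counts <- function(session, windows = analysis_windows()) {
  carbons <- sort(unique(session$trials$odour_carbon))
  uids <- vapply(session$units, `[[`, 1, "unit_id")
  out <- list()
  for (oc in carbons) {
    onsets <- session$trials$onset_s[session$trials$odour_carbon == oc]
    m <- matrix(0L, nrow = length(onsets), ncol = length(uids),
                dimnames = list(NULL, as.character(uids)))
    for (k in seq_along(session$units)) {
      st <- session$units[[k]]$spike_times
      for (i in seq_along(onsets)) {
        a <- onsets[i] + windows$odour_window[1]
        b <- onsets[i] + windows$odour_window[2]
        m[i, k] <- sum(st >= a & st < b)
      }
    }
    out[[as.character(oc)]] <- m
  }
  out
}

#' Compare feature distributions between two groups
#'
#' Two-sample comparison used for response features (peak z, width,
#' latency): with the normality gate on, both groups passing a Shapiro-Wilk
#' test at alpha = 0.05 selects a two-tailed two-sample t test, otherwise a
#' two-tailed Mann-Whitney U test.
#'
#' @param x,y numeric vectors (>= 3 values each).
#' @param test `"auto"` (gated), `"mann_whitney"`, or `"t_test"`.
#' @param normality_gate apply the normality gate when `test = "auto"`.
#' @return A `"test_result"` list: `statistic`, `p`, `test`, `tails`.
#' @export
compare_feature_distributions <- function(x, y,
                                          test = c("auto", "mann_whitney",
                                                   "t_test"),
                                          normality_gate = TRUE) {
  test <- match.arg(test)
  stopifnot(length(x) >= 3, length(y) >= 3)
  if (length(unique(c(x, y))) == 1) {
    stop("all values identical in both groups: comparison degenerate",
         call. = FALSE)
  }
  if (test == "auto") {
    normal <- normality_gate &&
      length(unique(x)) > 1 && length(unique(y)) > 1 &&
      stats::shapiro.test(x)$p.value > 0.05 &&
      stats::shapiro.test(y)$p.value > 0.05
    test <- if (normal) "t_test" else "mann_whitney"
  }
  if (test == "t_test") {
    tt <- stats::t.test(x, y, var.equal = FALSE)
    structure(list(statistic = unname(tt$statistic), p = tt$p.value,
                   test = "t_test", tails = "two"),
              class = "test_result")
  } else {
    r <- mann_whitney_u(x, y, tails = "two")
    r$test <- "mann_whitney"
    r
  }
}
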