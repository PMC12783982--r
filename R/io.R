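#' Write a session bundle to disk
#'
#' Serialises a recording session as a directory of comma-delimited text
#' tables -- `units.csv` (unit_id, tetrode_id, session_id, genotype,
#' region), `spikes.csv` (unit_id, spike_time_s), `trials.csv` (trial_id,
#' odour_carbon, onset_s, offset_s) -- plus a `manifest` (DCF text:
#' format version, session id, span, optional seed). Times are written at
#' 10 microsecond precision with deterministic formatting, so identical
#' sessions produce byte-identical bundles.
#'
#' @param session a `"recording_session"`.
#' @param path directory to create/write into.
#' @param seed optional generator seed recorded in the manifest.
#' @return `path`, invisibly.
#' @export
write_session_bundle <- function(session, path, seed = NA) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  fmt_t <- function(x) sprintf("%.5f", x)

  units <- if (length(session$units) == 0) {
    data.frame(unit_id = integer(0), tetrode_id = integer(0),
               session_id = character(0), genotype = character(0),
               region = character(0))
  } else {
    data.frame(
      unit_id = vapply(session$units, `[[`, 1, "unit_id"),
      tetrode_id = vapply(session$units, `[[`, 1, "tetrode_id"),
      session_id = session$session_id,
      genotype = session$genotype, region = session$region)
  }
  spikes <- do.call(rbind, c(list(
    data.frame(unit_id = integer(0), spike_time_s = character(0))),
    lapply(session$units, function(u) {
      if (length(u$spike_times) == 0) return(NULL)
      data.frame(unit_id = u$unit_id, spike_time_s = fmt_t(u$spike_times))
    })))
  trials <- data.frame(trial_id = session$trials$trial_id,
                       odour_carbon = session$trials$odour_carbon,
                       onset_s = fmt_t(session$trials$onset_s),
                       offset_s = fmt_t(session$trials$offset_s))

  utils::write.csv(units, file.path(path, "units.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(spikes, file.path(path, "spikes.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(trials, file.path(path, "trials.csv"), row.names = FALSE,
                   quote = FALSE)
  manifest <- matrix(c("1", session$session_id, fmt_t(session$span),
                       as.character(seed)), nrow = 1,
                     dimnames = list(NULL, c("format_version", "session_id",
                                             "span_s", "seed")))
  write.dcf(manifest, file.path(path, "manifest"))
  invisible(path)
}

#' Read a session bundle from disk
#'
#' Reads and validates the bundle written by [write_session_bundle()].
#' Validation covers referential integrity (every spike's unit exists),
#' odour carbon range, spike-time ordering within units, and trial
#' non-overlap; violations raise errors naming the offending rows.
#'
#' @param path bundle directory.
#' @return A `"recording_session"`.
#' @export
read_session_bundle <- function(path) {
  need <- c("units.csv", "spikes.csv", "trials.csv", "manifest")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing)) {
    stop("bundle at ", path, " is missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  units <- utils::read.csv(file.path(path, "units.csv"))
  spikes <- utils::read.csv(file.path(path, "spikes.csv"))
  trials <- utils::read.csv(file.path(path, "trials.csv"))
  manifest <- read.dcf(file.path(path, "manifest"))

  expect_cols <- function(df, cols, name) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop("table ", name, " lacks columns: ",
                           paste(miss, collapse = ", "), call. = FALSE)
  }
  expect_cols(units, c("unit_id", "tetrode_id", "session_id", "genotype",
                       "region"), "units")
  expect_cols(spikes, c("unit_id", "spike_time_s"), "spikes")
  expect_cols(trials, c("trial_id", "odour_carbon", "onset_s", "offset_s"),
              "trials")

  if (anyDuplicated(units$unit_id)) {
    stop("duplicate unit_id in units table", call. = FALSE)
  }
  bad <- setdiff(unique(spikes$unit_id), units$unit_id)
  if (length(bad)) {
    stop("spikes reference unknown unit_id: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad_carbon <- which(!(trials$odour_carbon %in% 3:8))
  if (length(bad_carbon)) {
    stop("trials rows ", paste(bad_carbon, collapse = ", "),
         " have odour_carbon outside 3..8", call. = FALSE)
  }
  o <- order(trials$onset_s)
  if (any(trials$offset_s[o][-nrow(trials)] > trials$onset_s[o][-1])) {
    stop("overlapping trials in trials table", call. = FALSE)
  }

  unit_list <- lapply(seq_len(nrow(units)), function(i) {
    st <- spikes$spike_time_s[spikes$unit_id == units$unit_id[i]]
    if (is.unsorted(st)) {
      stop("non-monotone spike times for unit ", units$unit_id[i],
           call. = FALSE)
    }
    list(unit_id = units$unit_id[i], tetrode_id = units$tetrode_id[i],
         spike_times = as.numeric(st))
  })
  structure(list(
    session_id = unname(manifest[1, "session_id"]),
    genotype = if (nrow(units)) units$genotype[1] else NA_character_,
    region = if (nrow(units)) units$region[1] else NA_character_,
    span = as.numeric(unname(manifest[1, "span_s"])),
    units = unit_list,
    trials = trials[, c("trial_id", "odour_carbon", "onset_s", "offset_s")]
  ), class = "recording_session")
}

#' Pipeline run configuration
#'
#' Collects every analysis default in one place: the analysis windows and
#' classification threshold, the unit-inclusion rate floor, the
#' spike-detection threshold factor, and the decoder settings (500
#' iterations per population size, sizes in steps of 10, projection to 4
#' dimensions, chance level 1/6 for six odours).
#'
#' @param windows an [analysis_windows()].
#' @param min_rate unit mean-rate inclusion floor (Hz).
#' @param detection_factor spike-detection threshold factor.
#' @param n_trials trials per odour in the pseudopopulation.
#' @param classifier decoder type.
#' @param iters decoder iterations per size.
#' @param size_step decoder population-size step.
#' @param pca_dim decoder target dimensionality.
#' @param knn_k neighbours for the kNN/ECOC control classifier.
#' @param omnibus omnibus test for the distance analysis.
#' @param seed integer seed for the decoder.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(windows = analysis_windows(), min_rate = 0.5,
                       detection_factor = 7.5, n_trials = 19L,
                       classifier = c("gaussian", "knn_ecoc"),
                       iters = 500L, size_step = 10L, pca_dim = 4L,
                       knn_k = 5L,
                       omnibus = c("welch", "brown_forsythe"), seed = 1L) {
  structure(list(windows = windows, min_rate = min_rate,
                 detection_factor = detection_factor,
                 n_trials = as.integer(n_trials),
                 classifier = match.arg(classifier),
                 iters = as.integer(iters), size_step = as.integer(size_step),
                 pca_dim = as.integer(pca_dim), knn_k = as.integer(knn_k),
                 omnibus = match.arg(omnibus), seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates the analysis stages over one or more sessions per
#' genotype: unit deduplication across sessions, z-score response
#' classification and response fractions, per-unit d', relative-response
#' tables with ranked and chain-distance curves and their two-way ANOVAs,
#' cross-odour population distances with omnibus and Games--Howell tests,
#' and the subsampled leave-one-trial-out decoding curve, per genotype.
#' When both genotypes are present, decoding curves are compared per size.
#'
#' @param sessions list of `"recording_session"` objects (possibly mixed
#'   genotypes), or a character vector of bundle directories.
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, tidy result tables are
#'   written as CSV.
#' @param decode run the decoding stage (the slowest; default TRUE).
#' @return List of class `"pipeline_report"` with elements `labels`,
#'   `fractions`, `dprimes`, `relative`, `ranked_curve`,
#'   `chain_curve`, `chain_anova`, `rank_anova`, `distances`, `decoding`,
#'   `decoding_comparison`, `log`.
#' @export
run_pipeline <- function(sessions, config = run_config(), out_dir = NULL,
                         decode = TRUE) {
  if (is.character(sessions)) {
    sessions <- lapply(sessions, read_session_bundle)
  }
  if (inherits(sessions, "recording_session")) sessions <- list(sessions)
  w <- config$windows
  log <- list(defaults = utils::capture.output(utils::str(config)))

  # tetrode deduplication applies within an animal's session series;
  # sessions of different genotypes come from different animals, so the
  # rule is applied per genotype group
  genos <- unique(vapply(sessions, `[[`, "", "genotype"))
  by_geno <- lapply(stats::setNames(genos, genos), function(g) {
    dedup_units(
      sessions[vapply(sessions, function(s) s$genotype == g, logical(1))])
  })
  sessions <- do.call(c, unname(by_geno))

  # globally unique unit ids for pooled tables
  pooled <- function(fn) {
    do.call(rbind, lapply(sessions, function(s) {
      d <- fn(s)
      d$unit_id <- paste0(s$session_id, "_u", d$unit_id)
      d
    }))
  }
  labels <- pooled(function(s) classify_responses(s, w))
  fractions <- response_fractions(labels)
  dprimes <- do.call(rbind, lapply(sessions, function(s) {
    dp <- unit_dprimes(s, w)$per_unit
    if (is.null(dp) || nrow(dp) == 0) return(NULL)
    dp$unit_id <- paste0(s$session_id, "_u", dp$unit_id)
    dp$genotype <- s$genotype
    dp
  }))
  strengths <- pooled(function(s) response_strengths(s, w))
  relative <- suppressWarnings(relative_responses(strengths))
  rc <- ranked_curve(relative)
  cc <- chain_distance_curve(relative)

  chain_anova <- NULL
  rank_anova <- NULL
  d_chain <- relative[relative$chain_distance > 0, ]
  if (length(genos) >= 2) {
    chain_anova <- two_way_anova(d_chain$relative_strength,
                                 d_chain$genotype, d_chain$chain_distance)
    d_rank <- relative[relative$rank > 1, ]
    rank_anova <- two_way_anova(d_rank$relative_strength, d_rank$genotype,
                                d_rank$rank, repeated_on = d_rank$unit_id)
  }

  distances <- lapply(by_geno, function(ss) {
    pop <- build_pseudopopulation(ss, config$n_trials, w)
    cross_odour_distances(pop, config$omnibus)
  })

  decoding <- NULL
  decoding_comparison <- NULL
  if (decode) {
    decoding <- lapply(by_geno, function(ss) {
      pop <- build_pseudopopulation(ss, config$n_trials, w)
      n <- ncol(pop$counts)
      sizes <- seq(config$size_step, n, by = config$size_step)
      decode_accuracy(pop, config$classifier, sizes = sizes,
                      iters = config$iters, pca_dim = config$pca_dim,
                      seed = config$seed, k = config$knn_k)
    })
    if (length(genos) >= 2) {
      a <- decoding[[1]]; b <- decoding[[2]]
      common <- intersect(a$sizes, b$sizes)
      trim <- function(cv, common) {
        keep <- cv$sizes %in% common
        cv$sizes <- cv$sizes[keep]
        cv$outcomes <- cv$outcomes[, keep, drop = FALSE]
        cv$accuracy <- cv$accuracy[keep]
        cv
      }
      decoding_comparison <- compare_decoding_curves(trim(a, common),
                                                     trim(b, common))
      names(decoding_comparison)[2:3] <- paste0("acc_", names(decoding)[1:2])
    }
  }

  report <- structure(list(labels = labels, fractions = fractions,
                           dprimes = dprimes, relative = relative,
                           ranked_curve = rc, chain_curve = cc,
                           chain_anova = chain_anova,
                           rank_anova = rank_anova,
                           distances = distances, decoding = decoding,
                           decoding_comparison = decoding_comparison,
                           log = log),
                      class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, f) {
    if (!is.null(d)) utils::write.csv(d, file.path(out_dir, f),
                                      row.names = FALSE)
  }
  wcsv(report$labels, "unit_odour_labels.csv")
  wcsv(report$fractions, "response_fractions.csv")
  wcsv(report$dprimes, "unit_dprimes.csv")
  wcsv(report$relative, "relative_responses.csv")
  wcsv(report$ranked_curve, "ranked_curve.csv")
  wcsv(report$chain_curve, "chain_distance_curve.csv")
  if (!is.null(report$chain_anova)) {
    wcsv(report$chain_anova$effects, "chain_anova.csv")
  }
  if (!is.null(report$rank_anova)) {
    wcsv(report$rank_anova$effects, "rank_anova.csv")
  }
  for (g in names(report$decoding)) {
    cv <- report$decoding[[g]]
    wcsv(data.frame(size = cv$sizes, accuracy = cv$accuracy,
                    binomial_p = cv$binomial_p, chance = cv$chance),
         paste0("decoding_", g, ".csv"))
  }
  wcsv(report$decoding_comparison, "decoding_comparison.csv")
  invisible(out_dir)
}
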