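#' Per unit-odour response strengths
#'
#' Response strength of a unit to an odour, defined as the trial-averaged
#' spike rate (Hz) in the odour window (raw rate, not baseline-subtracted,
#' so relative strengths lie in [0, 1]).
#'
#' @param session a `"recording_session"`.
#' @param windows an [analysis_windows()].
#' @return Data frame `unit_id`, `odour_carbon`, `strength`, plus session
#'   `genotype` and `region`.
#' @export
response_strengths <- function(session, windows = analysis_windows()) {
  counts <- odour_window_counts(session, windows)
  dur <- diff(windows$odour_window)
  carbons <- sort(unique(session$trials$odour_carbon))
  uids <- vapply(session$units, `[[`, 1, "unit_id")
  rows <- lapply(carbons, function(oc) {
    data.frame(unit_id = uids, odour_carbon = oc,
               strength = colMeans(counts[[as.character(oc)]]) / dur,
               genotype = session$genotype, region = session$region)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$unit_id, out$odour_carbon), ]
}

#' Relative odour responses per unit
#'
#' Identifies each unit's strongest odour response and normalises the
#' responses to the remaining odours by it, assigning response ranks and
#' carbon-chain distances from the best odour. Ties for the best odour are
#' broken deterministically by the lower carbon number. Units whose
#' strengths are all zero are excluded (normalisation undefined) with a
#' warning.
#'
#' @param strengths data frame from [response_strengths()] (rows from
#'   several sessions may be concatenated; unit ids must be unique).
#' @return Data frame with `unit_id`, `odour_carbon`, `strength`,
#'   `relative_strength` in [0, 1], `best_odour_flag`, `rank` (1..n
#'   odours), `chain_distance`, and any `genotype`/`region` columns.
#' @export
relative_responses <- function(strengths) {
  stopifnot(nrow(strengths) >= 1)
  sp <- split(strengths, strengths$unit_id)
  dropped <- 0L
  out <- lapply(sp, function(d) {
    if (all(d$strength == 0)) {
      dropped <<- dropped + 1L
      return(NULL)
    }
    d <- d[order(d$odour_carbon), ]
    best_i <- which(d$strength == max(d$strength))[1]  # lowest carbon wins
    d$relative_strength <- d$strength / d$strength[best_i]
    d$best_odour_flag <- seq_len(nrow(d)) == best_i
    # rank by strength descending, ties by lower carbon (order is stable)
    d$rank <- NA_integer_
    d$rank[order(-d$strength, d$odour_carbon)] <- seq_len(nrow(d))
    d$chain_distance <- abs(d$odour_carbon - d$odour_carbon[best_i])
    d
  })
  if (dropped > 0) {
    warning(dropped, " unit(s) with all-zero strengths excluded")
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Ranked response curve
#'
#' Mean relative response strength as a function of response rank, per
#' genotype when a genotype column is present. Rank 1 is identically 1 by
#' construction and can be excluded for repeated-measures testing.
#'
#' @param table output of [relative_responses()].
#' @param exclude_rank_1 drop rank-1 entries.
#' @return Data frame `genotype` (if present), `rank`, `mean_relative`,
#'   `n`.
#' @export
ranked_curve <- function(table, exclude_rank_1 = FALSE) {
  d <- table
  if (exclude_rank_1) d <- d[d$rank > 1, ]
  by <- if ("genotype" %in% names(d)) list(genotype = d$genotype,
                                           rank = d$rank)
  else list(rank = d$rank)
  agg <- aggregate(d$relative_strength, by = by,
                   FUN = function(v) c(mean = mean(v), n = length(v)))
  out <- data.frame(agg[setdiff(names(agg), "x")],
                    mean_relative = agg$x[, "mean"], n = agg$x[, "n"])
  out[order(out$rank), ]
}

#' Chemical-distance response curve
#'
#' Mean relative response strength as a function of the absolute
#' carbon-chain-length difference from each unit's best odour, per
#' genotype when present. The best odour itself (distance 0, relative 1 by
#' construction) is excluded. Cell counts differ across distances because
#' each unit's best odour determines which distances it contributes.
#'
#' @param table output of [relative_responses()].
#' @return Data frame `genotype` (if present), `chain_distance`,
#'   `mean_relative`, `n`.
#' @export
chain_distance_curve <- function(table) {
  d <- table[table$chain_distance > 0, ]
  by <- if ("genotype" %in% names(d)) list(genotype = d$genotype,
                                           chain_distance = d$chain_distance)
  else list(chain_distance = d$chain_distance)
  agg <- aggregate(d$relative_strength, by = by,
                   FUN = function(v) c(mean = mean(v), n = length(v)))
  out <- data.frame(agg[setdiff(names(agg), "x")],
                    mean_relative = agg$x[, "mean"], n = agg$x[, "n"])
  out[order(out$chain_distance), ]
}

#' Two-way ANOVA with Sidak post-hocs
#'
#' Fixed-effects two-way ANOVA (with interaction) of `values` on factors
#' `a` (e.g. genotype) and `b` (e.g. chain distance or response rank),
#' using Type II sums of squares for unbalanced tables. When
#' `repeated_on` supplies a subject (unit) identifier, a repeated-measures
#' ANOVA is fitted instead, with `a` as the between-subject and `b` as the
#' within-subject factor (subject variance partitioned out of the within
#' stratum). Pairwise Sidak-adjusted post-hoc comparisons across the
#' levels of `b` are computed within each level of `a` using Welch t
#' tests.
#'
#' @param values numeric response vector.
#' @param a,b factors (coerced); >= 2 levels each, no empty cell.
#' @param repeated_on optional subject identifier vector for the
#'   repeated-measures variant (each subject must contribute one value per
#'   level of `b`).
#' @return List of class `"similarity_anova"`: `effects` (data frame with
#'   term, df1, df2, F, p), `posthoc` (per level of `a`, a symmetric
#'   matrix of Sidak-adjusted p across levels of `b`), `type`.
#' @export
two_way_anova <- function(values, a, b, repeated_on = NULL) {
  a <- factor(a); b <- factor(b)
  stopifnot(length(values) == length(a), length(a) == length(b))
  if (nlevels(a) < 2 && nlevels(b) < 2) {
    stop("need >= 2 levels in at least one factor", call. = FALSE)
  }
  # one-way reduction when a factor is constant
  if (nlevels(a) < 2 || nlevels(b) < 2) {
    f <- if (nlevels(a) >= 2) a else b
    if (stats::var(values) == 0) {
      stop("all values identical: F undefined", call. = FALSE)
    }
    an <- stats::anova(stats::lm(values ~ f))
    effects <- data.frame(term = if (nlevels(a) >= 2) "a" else "b",
                          df1 = an[1, "Df"], df2 = an[2, "Df"],
                          F = an[1, "F value"], p = an[1, "Pr(>F)"])
    return(structure(list(effects = effects, posthoc = NULL,
                          type = "one_way_reduction"),
                     class = "similarity_anova"))
  }
  tab <- table(a, b)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop("empty cell: a = ", levels(a)[empty[1]], ", b = ",
         levels(b)[empty[2]], call. = FALSE)
  }
  if (stats::var(values) == 0) {
    stop("all values identical: F undefined", call. = FALSE)
  }

  if (is.null(repeated_on)) {
    fit <- stats::lm(values ~ a * b)
    an <- car::Anova(fit, type = 2)
    terms <- rownames(an)
    keep <- terms != "Residuals"
    df2 <- an[terms == "Residuals", "Df"]
    effects <- data.frame(term = c("a", "b", "a:b")[seq_len(sum(keep))],
                          df1 = an[keep, "Df"], df2 = df2,
                          F = an[keep, "F value"],
                          p = an[keep, "Pr(>F)"])
    type <- "fixed"
  } else {
    subj <- factor(repeated_on)
    df <- data.frame(values = values, a = a, b = b, subj = subj)
    fit <- stats::aov(values ~ a * b + Error(subj), data = df)
    sm <- summary(fit)
    eff <- list()
    for (stratum in sm) {
      st <- stratum[[1]]
      rn <- trimws(rownames(st))
      for (i in seq_along(rn)) {
        if (rn[i] == "Residuals") next
        resid_df <- st[rn == "Residuals", "Df"]
        eff[[rn[i]]] <- data.frame(term = rn[i], df1 = st[i, "Df"],
                                   df2 = resid_df, F = st[i, "F value"],
                                   p = st[i, "Pr(>F)"])
      }
    }
    effects <- do.call(rbind, eff)
    rownames(effects) <- NULL
    type <- "repeated"
  }

  posthoc <- lapply(stats::setNames(levels(a), levels(a)), function(al) {
    lv <- levels(b)
    m <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
    pairs <- utils::combn(length(lv), 2)
    n_pairs <- ncol(pairs)
    for (pi in seq_len(n_pairs)) {
      i <- pairs[1, pi]; j <- pairs[2, pi]
      x <- values[a == al & b == lv[i]]
      y <- values[a == al & b == lv[j]]
      raw <- if (length(x) < 2 || length(y) < 2) {
        NA_real_  # cell too small for a pairwise comparison
      } else if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        if (mean(x) == mean(y)) 1 else 0
      } else {
        stats::t.test(x, y, var.equal = FALSE)$p.value
      }
      m[i, j] <- m[j, i] <- sidak_adjust(raw, n_pairs)
    }
    diag(m) <- 1
    m
  })

  structure(list(effects = effects, posthoc = posthoc, type = type),
            class = "similarity_anova")
}
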