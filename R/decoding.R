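#' Build a pseudopopulation spike-count matrix
#'
#' Pools units across sessions into one trials x units matrix of
#' odour-window spike counts. Rows are aligned across sessions by
#' within-odour trial index: row r of odour o combines each session's r-th
#' trial of odour o (sessions are not simultaneous, so this is a
#' pseudopopulation). The first `n_trials` trials of each odour are used.
#'
#' @param sessions list of `"recording_session"` objects (deduplicate
#'   repeated tetrodes first with [dedup_units()]).
#' @param n_trials trials per odour retained (default 19); every session
#'   must have at least this many trials of every odour.
#' @param windows an [analysis_windows()].
#' @return List of class `"population_matrix"`: `counts` (matrix, rows =
#'   odours x trials, columns = units), `odour` (carbon per row),
#'   `trial_index` (within-odour index per row), `unit_key` (data frame
#'   session/unit per column).
#' @export
build_pseudopopulation <- function(sessions, n_trials = 19L,
                                   windows = analysis_windows()) {
  if (inherits(sessions, "recording_session")) sessions <- list(sessions)
  carbons <- sort(unique(sessions[[1]]$trials$odour_carbon))
  blocks <- list()
  keys <- list()
  for (s in sessions) {
    cnt <- odour_window_counts(s, windows)
    per_odour <- list()
    for (oc in carbons) {
      m <- cnt[[as.character(oc)]]
      if (is.null(m) || nrow(m) < n_trials) {
        stop("session ", s$session_id, " has fewer than ", n_trials,
             " trials of odour carbon ", oc, call. = FALSE)
      }
      per_odour[[as.character(oc)]] <- m[seq_len(n_trials), , drop = FALSE]
    }
    blocks[[length(blocks) + 1L]] <- do.call(rbind, per_odour)
    keys[[length(keys) + 1L]] <- data.frame(
      session_id = s$session_id,
      unit_id = vapply(s$units, `[[`, 1, "unit_id"))
  }
  counts <- do.call(cbind, blocks)
  odour <- rep(carbons, each = n_trials)
  structure(list(counts = counts, odour = odour,
                 trial_index = rep(seq_len(n_trials), times = length(carbons)),
                 unit_key = do.call(rbind, keys)),
            class = "population_matrix")
}

#' Cross-odour population-vector distances
#'
#' Euclidean distances between the population vectors of every pair of
#' trials, partitioned into within-odour distributions (trial-to-trial
#' variability of one odour) and cross-odour distributions (one per odour
#' pair). The 6 + 15 = 21 groups are compared with a heteroscedastic
#' one-way ANOVA (Welch by default, Brown--Forsythe selectable) followed by
#' Games--Howell post-hoc tests; the post-hoc grid reports, for each
#' row-odour, its within-odour distribution against each cross-odour
#' distribution.
#'
#' @param pop a `"population_matrix"`.
#' @param omnibus `"welch"` or `"brown_forsythe"`.
#' @return List of class `"distance_summary"`: `groups` (named list of
#'   distance vectors; names `"w<c>"` within, `"x<a>_<b>"` cross),
#'   `omnibus` (a `"test_result"`, or NULL if degenerate), `games_howell`
#'   (full pairwise result), `grid` (odour x odour matrix of adjusted p:
#'   within-row-odour vs cross), `degenerate` flag.
#' @export
cross_odour_distances <- function(pop, omnibus = c("welch",
                                                   "brown_forsythe")) {
  omnibus <- match.arg(omnibus)
  carbons <- sort(unique(pop$odour))
  if (length(carbons) < 2) stop("need >= 2 odours", call. = FALSE)
  dm <- as.matrix(stats::dist(pop$counts))
  groups <- list()
  for (i in seq_along(carbons)) {
    ri <- which(pop$odour == carbons[i])
    w <- dm[ri, ri][upper.tri(dm[ri, ri])]
    groups[[paste0("w", carbons[i])]] <- w
    for (j in seq_along(carbons)) {
      if (j <= i) next
      rj <- which(pop$odour == carbons[j])
      groups[[paste0("x", carbons[i], "_", carbons[j])]] <-
        as.vector(dm[ri, rj])
    }
  }
  vs <- vapply(groups, function(g) {
    if (length(g) < 2) NA_real_ else stats::var(g)
  }, numeric(1))
  degenerate <- all(unlist(groups) == 0) || anyNA(vs) || any(vs == 0)
  om <- NULL
  gh <- NULL
  grid <- matrix(NA_real_, length(carbons), length(carbons),
                 dimnames = list(carbons, carbons))
  if (!degenerate) {
    om <- if (omnibus == "welch") welch_anova(groups)
    else brown_forsythe_anova(groups)
    gh <- games_howell(groups)
    for (i in seq_along(carbons)) {
      for (j in seq_along(carbons)) {
        if (i == j) next
        key <- if (i < j) paste0("x", carbons[i], "_", carbons[j])
        else paste0("x", carbons[j], "_", carbons[i])
        grid[i, j] <- gh$p[paste0("w", carbons[i]), key]
      }
    }
  }
  structure(list(groups = groups, omnibus = om, games_howell = gh,
                 grid = grid, degenerate = degenerate),
            class = "distance_summary")
}

#' Gaussian mixture odour classifier
#'
#' Fits a Gaussian mixture with known component labels and equal priors:
#' one mean per odour class and, by default, a single full covariance
#' pooled across classes (`covariance = "pooled"`). A per-class full
#' covariance is available (`covariance = "class"`), but under
#' leave-one-trial-out evaluation class-wise covariances make the
#' held-out trial repel its own class's fitted parameters, biasing null
#' accuracy below chance; the pooled form is chance-calibrated. A small
#' diagonal regularisation keeps covariances invertible. Prediction
#' assigns the class of maximal likelihood; ties break to the lowest
#' carbon number.
#'
#' @param x training matrix (rows = trials, columns = dimensions).
#' @param labels class label (odour carbon) per row.
#' @param covariance `"pooled"` (shared full covariance) or `"class"`
#'   (one full covariance per class).
#' @param reg diagonal regularisation as a fraction of the mean pooled
#'   variance (default 1e-6).
#' @return Model of class `"gaussian_classifier"`.
#' @export
fit_gaussian_classifier <- function(x, labels,
                                    covariance = c("pooled", "class"),
                                    reg = 1e-6) {
  covariance <- match.arg(covariance)
  x <- as.matrix(x)
  classes <- sort(unique(labels))
  d <- ncol(x)
  eps <- reg * mean(apply(x, 2, stats::var))
  if (!is.finite(eps) || eps <= 0) eps <- reg
  chol_or_stop <- function(S, what) {
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) stop("singular covariance (", what, ")", call. = FALSE)
    ch
  }
  if (covariance == "pooled") {
    if (nrow(x) - length(classes) < d + 1) {
      stop("too few training rows for a pooled ", d,
           "-dimensional covariance", call. = FALSE)
    }
    S_acc <- matrix(0, d, d)
    means <- list()
    for (cl in classes) {
      xi <- x[labels == cl, , drop = FALSE]
      means[[as.character(cl)]] <- colMeans(xi)
      S_acc <- S_acc + stats::cov(xi) * (nrow(xi) - 1)
    }
    S <- S_acc / (nrow(x) - length(classes)) + diag(eps, d)
    ch <- chol_or_stop(S, "pooled")
    logdet <- 2 * sum(log(diag(ch)))
    fits <- lapply(classes, function(cl) {
      list(mean = means[[as.character(cl)]], chol = ch, logdet = logdet)
    })
  } else {
    fits <- lapply(classes, function(cl) {
      xi <- x[labels == cl, , drop = FALSE]
      if (nrow(xi) < d + 2) {
        stop("class ", cl, " has too few training rows (", nrow(xi),
             ") for a ", d, "-dimensional covariance", call. = FALSE)
      }
      S <- stats::cov(xi) + diag(eps, d)
      ch <- chol_or_stop(S, paste("class", cl))
      list(mean = colMeans(xi), chol = ch, logdet = 2 * sum(log(diag(ch))))
    })
  }
  structure(list(classes = classes, fits = fits, d = d,
                 covariance = covariance),
            class = "gaussian_classifier")
}

#' @rdname fit_gaussian_classifier
#' @param object a fitted classifier.
#' @param newx numeric vector (one observation) or matrix of observations.
#' @param ... unused.
#' @return `predict`: predicted class label(s).
#' @export
predict.gaussian_classifier <- function(object, newx, ...) {
  newx <- if (is.null(dim(newx))) matrix(newx, nrow = 1) else as.matrix(newx)
  ll <- vapply(object$fits, function(f) {
    z <- forwardsolve(t(f$chol), t(newx) - f$mean)
    -0.5 * (colSums(z^2) + f$logdet)
  }, numeric(nrow(newx)))
  ll <- matrix(ll, nrow = nrow(newx))
  apply(ll, 1, function(r) object$classes[which.max(r)])
}

#' kNN error-correcting output codes classifier
#'
#' Multiclass classification via one-vs-one error-correcting output codes:
#' one binary k-nearest-neighbour learner (Euclidean metric, majority
#' vote) per class pair, combined by minimal Hamming-style loss over the
#' coding matrix. Ties break to the lowest carbon number.
#'
#' @param x training matrix.
#' @param labels class label per row.
#' @param k number of neighbours (default 5); must not exceed the smallest
#'   binary-problem training size.
#' @return Model of class `"knn_ecoc"`.
#' @export
fit_knn_ecoc <- function(x, labels, k = 5L) {
  x <- as.matrix(x)
  classes <- sort(unique(labels))
  n_per <- table(labels)
  if (k < 1 || k > 2 * min(n_per)) {
    stop("invalid k = ", k, " for smallest binary problem of size ",
         2 * min(n_per), call. = FALSE)
  }
  structure(list(x = x, labels = labels, classes = classes, k = as.integer(k)),
            class = "knn_ecoc")
}

#' @rdname fit_knn_ecoc
#' @param object a fitted `"knn_ecoc"`.
#' @param newx one observation (vector) or a matrix of observations.
#' @param ... unused.
#' @return `predict`: predicted class label(s).
#' @export
predict.knn_ecoc <- function(object, newx, ...) {
  newx <- if (is.null(dim(newx))) matrix(newx, nrow = 1) else as.matrix(newx)
  classes <- object$classes
  nc <- length(classes)
  pairs <- utils::combn(nc, 2)
  apply(newx, 1, function(q) {
    d2 <- colSums((t(object$x) - q)^2)
    votes <- numeric(nc)
    for (pi in seq_len(ncol(pairs))) {
      i <- pairs[1, pi]; j <- pairs[2, pi]
      in_pair <- object$labels %in% classes[c(i, j)]
      dp <- d2[in_pair]
      lp <- object$labels[in_pair]
      nn <- order(dp)[seq_len(min(object$k, length(dp)))]
      vi <- sum(lp[nn] == classes[i])
      winner <- if (vi * 2 > length(nn)) i
      else if (vi * 2 < length(nn)) j
      else min(i, j)  # tied vote -> lower carbon
      votes[winner] <- votes[winner] + 1
    }
    classes[which.max(votes)]  # ties -> first (lowest carbon)
  })
}

#' Subsampled leave-one-trial-out decoding curve
#'
#' The full odour-decoding pipeline: for each population size, repeatedly
#' (i) draw a random subsample of units, (ii) hold out one random trial,
#' (iii) reduce the training rows to `pca_dim` dimensions with PCA (fit on
#' the training rows only, unless `pca_on_train_only = FALSE`, which
#' reproduces the literal reduce-all-then-hold-out reading), (iv) fit the
#' classifier on the projected training rows, and (v) score the projected
#' held-out trial. Accuracy per size is the fraction of correct
#' predictions over iterations, with a one-sided exact binomial test
#' against chance (1 / number of odour classes).
#'
#' @param pop a `"population_matrix"`.
#' @param classifier `"gaussian"` or `"knn_ecoc"`.
#' @param sizes population sizes to test (default `seq(10, N, 10)`).
#' @param iters iterations per size (default 500).
#' @param pca_dim target dimensionality (default 4).
#' @param seed integer seed.
#' @param k neighbours for the kNN/ECOC classifier.
#' @param pca_on_train_only fit the projection on training rows only
#'   (default TRUE); `FALSE` reduces all trials jointly before the
#'   hold-out.
#' @param covariance covariance structure of the Gaussian classifier
#'   (see [fit_gaussian_classifier()]).
#' @return List of class `"decoding_curve"`: `sizes`, `accuracy`,
#'   `outcomes` (iters x sizes logical matrix), `chance`, `binomial_p` per
#'   size, `classifier`, `iters`, `seed`.
#' @export
decode_accuracy <- function(pop, classifier = c("gaussian", "knn_ecoc"),
                            sizes = NULL, iters = 500L, pca_dim = 4L,
                            seed = 1L, k = 5L, pca_on_train_only = TRUE,
                            covariance = c("pooled", "class")) {
  covariance <- match.arg(covariance)
  classifier <- match.arg(classifier)
  counts <- pop$counts
  n_units <- ncol(counts)
  n_rows <- nrow(counts)
  if (is.null(sizes)) sizes <- seq(10L, n_units, by = 10L)
  if (any(sizes > n_units)) {
    stop("requested size exceeds available units (", n_units, ")",
         call. = FALSE)
  }
  if (any(pca_dim > sizes)) {
    stop("pca_dim exceeds smallest population size", call. = FALSE)
  }
  chance <- 1 / length(unique(pop$odour))
  set.seed(seed)
  outcomes <- matrix(NA, nrow = iters, ncol = length(sizes),
                     dimnames = list(NULL, sizes))
  for (si in seq_along(sizes)) {
    sz <- sizes[si]
    for (it in seq_len(iters)) {
      cols <- sample.int(n_units, sz)
      test_row <- sample.int(n_rows, 1)
      sub <- counts[, cols, drop = FALSE]
      if (pca_on_train_only) {
        train <- sub[-test_row, , drop = FALSE]
        pc <- stats::prcomp(train, center = TRUE, scale. = FALSE,
                            rank. = pca_dim)
        train_p <- pc$x[, seq_len(pca_dim), drop = FALSE]
        test_p <- (sub[test_row, ] - pc$center) %*%
          pc$rotation[, seq_len(pca_dim), drop = FALSE]
      } else {
        pc <- stats::prcomp(sub, center = TRUE, scale. = FALSE,
                            rank. = pca_dim)
        all_p <- pc$x[, seq_len(pca_dim), drop = FALSE]
        train_p <- all_p[-test_row, , drop = FALSE]
        test_p <- all_p[test_row, , drop = FALSE]
      }
      train_lab <- pop$odour[-test_row]
      model <- if (classifier == "gaussian") {
        fit_gaussian_classifier(train_p, train_lab, covariance = covariance)
      } else {
        fit_knn_ecoc(train_p, train_lab, k = k)
      }
      pred <- predict(model, as.numeric(test_p))
      outcomes[it, si] <- pred == pop$odour[test_row]
    }
  }
  accuracy <- colMeans(outcomes)
  binom_p <- vapply(seq_along(sizes), function(si) {
    binomial_test_one_sided(sum(outcomes[, si]), iters, chance,
                            "greater")$p
  }, numeric(1))
  structure(list(sizes = sizes, accuracy = unname(accuracy),
                 outcomes = outcomes, chance = chance,
                 binomial_p = binom_p, classifier = classifier,
                 iters = iters, seed = seed),
            class = "decoding_curve")
}

#' Compare two decoding curves
#'
#' Per-size two-proportion comparison of correct-prediction counts between
#' two decoding curves (same sizes and iteration counts), with Sidak
#' adjustment across sizes.
#'
#' @param curve_a,curve_b `"decoding_curve"` objects.
#' @return Data frame `size`, `acc_a`, `acc_b`, `diff`, `p`, `p_adj`.
#' @export
compare_decoding_curves <- function(curve_a, curve_b) {
  if (!identical(curve_a$sizes, curve_b$sizes) ||
      curve_a$iters != curve_b$iters) {
    stop("curves have mismatched sizes or iteration counts", call. = FALSE)
  }
  n <- curve_a$iters
  m <- length(curve_a$sizes)
  p_raw <- vapply(seq_len(m), function(i) {
    ka <- sum(curve_a$outcomes[, i]); kb <- sum(curve_b$outcomes[, i])
    if (ka == kb) return(1)
    suppressWarnings(stats::prop.test(c(ka, kb), c(n, n))$p.value)
  }, numeric(1))
  data.frame(size = curve_a$sizes,
             acc_a = curve_a$accuracy, acc_b = curve_b$accuracy,
             diff = curve_a$accuracy - curve_b$accuracy,
             p = p_raw, p_adj = sidak_adjust(p_raw, m))
}
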