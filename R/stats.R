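#' Welch's heteroscedastic one-way ANOVA
#'
#' Compares k group means without assuming equal variances, using Welch's
#' F statistic with Welch--Satterthwaite denominator degrees of freedom.
#'
#' @param groups list of numeric vectors (k >= 2, each n >= 2 with
#'   positive variance).
#' @return A `"test_result"`: `statistic` (F), `df` = c(df1, df2), `p`.
#' @export
welch_anova <- function(groups) {
  check_groups(groups)
  k <- length(groups)
  n <- vapply(groups, length, numeric(1))
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, stats::var, numeric(1))
  if (any(v == 0)) stop("zero-variance group", call. = FALSE)
  w <- n / v
  W <- sum(w)
  mw <- sum(w * m) / W
  tmp <- sum((1 - w / W)^2 / (n - 1))
  num <- sum(w * (m - mw)^2) / (k - 1)
  den <- 1 + 2 * (k - 2) / (k^2 - 1) * tmp
  f <- num / den
  df2 <- (k^2 - 1) / (3 * tmp)
  structure(list(statistic = f, df = c(k - 1, df2),
                 p = stats::pf(f, k - 1, df2, lower.tail = FALSE),
                 test = "welch_anova", tails = "one"),
            class = "test_result")
}

#' Brown--Forsythe one-way ANOVA
#'
#' The Brown--Forsythe F* statistic for comparing group means under
#' heteroscedasticity: between-group sum of squares over
#' `sum((1 - n_i/N) * s_i^2)`, with Satterthwaite denominator degrees of
#' freedom.
#'
#' @inheritParams welch_anova
#' @return A `"test_result"`.
#' @export
brown_forsythe_anova <- function(groups) {
  check_groups(groups)
  k <- length(groups)
  n <- vapply(groups, length, numeric(1))
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, stats::var, numeric(1))
  if (any(v == 0)) stop("zero-variance group", call. = FALSE)
  N <- sum(n)
  gm <- sum(n * m) / N
  num <- sum(n * (m - gm)^2)
  denom_terms <- (1 - n / N) * v
  den <- sum(denom_terms)
  if (num == 0) {
    return(structure(list(statistic = 0, df = c(k - 1, NA_real_), p = 1,
                          test = "brown_forsythe_anova", tails = "one"),
                     class = "test_result"))
  }
  f <- num / den
  c_i <- denom_terms / den
  df2 <- 1 / sum(c_i^2 / (n - 1))
  structure(list(statistic = f, df = c(k - 1, df2),
                 p = stats::pf(f, k - 1, df2, lower.tail = FALSE),
                 test = "brown_forsythe_anova", tails = "one"),
            class = "test_result")
}

#' Games--Howell post-hoc pairwise comparisons
#'
#' Pairwise comparisons for unequal variances and sample sizes: per pair a
#' Welch-type t statistic with Welch degrees of freedom, referred to the
#' studentized-range distribution with `q = t * sqrt(2)` and the total
#' number of groups, giving adjusted p-values.
#'
#' @param groups named list of numeric vectors (k >= 2).
#' @return List with `p` (symmetric k x k adjusted p matrix), `q`
#'   (statistics), `df` (Welch df per pair). Degenerate pairs (zero pooled
#'   variance) are `NA`.
#' @export
games_howell <- function(groups) {
  check_groups(groups)
  k <- length(groups)
  labs <- names(groups)
  if (is.null(labs)) labs <- as.character(seq_len(k))
  n <- vapply(groups, length, numeric(1))
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, stats::var, numeric(1))
  p <- q <- df <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se2 <- v[i] / n[i] + v[j] / n[j]
      if (se2 == 0) {
        if (m[i] == m[j]) { p[i, j] <- p[j, i] <- 1 }
        next
      }
      t_ij <- abs(m[i] - m[j]) / sqrt(se2)
      df_ij <- se2^2 / (v[i]^2 / (n[i]^2 * (n[i] - 1)) +
                          v[j]^2 / (n[j]^2 * (n[j] - 1)))
      q_ij <- t_ij * sqrt(2)
      p_ij <- stats::ptukey(q_ij, nmeans = k, df = df_ij,
                            lower.tail = FALSE)
      p[i, j] <- p[j, i] <- p_ij
      q[i, j] <- q[j, i] <- q_ij
      df[i, j] <- df[j, i] <- df_ij
    }
  }
  diag(p) <- 1
  list(p = p, q = q, df = df, k = k)
}

#' Mann--Whitney U test
#'
#' Rank-sum comparison of two samples. For `n_a * n_b <= 200` the null
#' distribution of U is obtained by exact enumeration of all group
#' labelings (valid under ties); larger problems use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b numeric vectors (each n >= 1).
#' @param tails `"two"`, `"less"`, or `"greater"` (direction refers to `a`
#'   tending to smaller/larger values than `b`).
#' @return A `"test_result"`: `statistic` (U for sample `a`), `p`, `exact`.
#' @export
mann_whitney_u <- function(a, b, tails = c("two", "less", "greater")) {
  tails <- match.arg(tails)
  if (length(a) < 1 || length(b) < 1) stop("empty group", call. = FALSE)
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  exact <- na * nb <= 200
  if (exact) {
    # exact null distribution of the rank sum by subset-sum counting over
    # the observed (mid)ranks; valid under ties. Ranks doubled -> integers.
    r2 <- as.integer(round(2 * r))
    S <- sum(sort(r2, decreasing = TRUE)[seq_len(na)])
    dp <- matrix(0, nrow = na + 1, ncol = S + 1)
    dp[1, 1] <- 1
    for (val in r2) {
      for (c_i in na:1) {  # iterate chosen-count downwards
        src <- dp[c_i, ]
        nz <- which(src != 0)
        if (length(nz)) {
          tgt <- nz + val
          ok <- tgt <= S + 1
          dp[c_i + 1, tgt[ok]] <- dp[c_i + 1, tgt[ok]] + src[nz[ok]]
        }
      }
    }
    counts <- dp[na + 1, ]
    sums2 <- seq_along(counts) - 1  # doubled rank-sum values
    us <- sums2 / 2 - na * (na + 1) / 2
    total <- sum(counts)
    center <- na * nb / 2
    p <- switch(tails,
      two = sum(counts[abs(us - center) >= abs(u_a - center) - 1e-9]) / total,
      greater = sum(counts[us >= u_a - 1e-9]) / total,
      less = sum(counts[us <= u_a + 1e-9]) / total)
  } else {
    ties <- table(r)
    n <- na + nb
    mu <- na * nb / 2
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    sigma <- sqrt(sigma2)
    z_upper <- (u_a - mu - 0.5) / sigma
    z_lower <- (u_a - mu + 0.5) / sigma
    p <- switch(tails,
      two = min(1, 2 * min(stats::pnorm(z_upper, lower.tail = FALSE),
                           stats::pnorm(z_lower))),
      greater = stats::pnorm(z_upper, lower.tail = FALSE),
      less = stats::pnorm(z_lower))
  }
  structure(list(statistic = u_a, p = p, test = "mann_whitney_u",
                 tails = tails, exact = exact),
            class = "test_result")
}

#' One-sided exact binomial test
#'
#' Exact binomial tail probability, used to test decoding accuracy against
#' chance level.
#'
#' @param successes number of successes (0..n).
#' @param n number of trials.
#' @param p0 null success probability in (0, 1).
#' @param direction `"greater"` for `P(X >= k)`, `"less"` for `P(X <= k)`.
#' @return A `"test_result"`: `statistic` (successes), `p`.
#' @export
binomial_test_one_sided <- function(successes, n, p0,
                                    direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (n < 1 || successes < 0 || successes > n || p0 <= 0 || p0 >= 1) {
    stop("invalid binomial test inputs", call. = FALSE)
  }
  p <- if (direction == "greater") {
    stats::pbinom(successes - 1, n, p0, lower.tail = FALSE)
  } else {
    stats::pbinom(successes, n, p0)
  }
  structure(list(statistic = successes, p = p, test = "binomial_one_sided",
                 tails = direction),
            class = "test_result")
}

#' Sidak adjustment for multiple comparisons
#'
#' `p_adj = 1 - (1 - p)^m`, clipped to `[0, 1]`.
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @param m number of comparisons in the family; must be at least the
#'   number of p-values supplied.
#' @return Adjusted p-values.
#' @export
sidak_adjust <- function(p_values, m = length(p_values)) {
  if (m < length(p_values)) {
    stop("m must be >= the number of tests", call. = FALSE)
  }
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  pmin(1, pmax(0, 1 - (1 - p_values)^m))
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a list of >= 2 groups", call. = FALSE)
  }
  n <- vapply(groups, length, numeric(1))
  if (any(n < 2)) stop("each group needs n >= 2", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$test, ": statistic = ", format(x$statistic, digits = 4), sep = "")
  if (!is.null(x$df)) cat(", df = (", paste(format(x$df, digits = 4),
                                            collapse = ", "), ")", sep = "")
  cat(", p = ", format(x$p, digits = 4), " [", x$tails, "-tailed]\n",
      sep = "")
  invisible(x)
}
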