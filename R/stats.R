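#' @name mea_tests
#' @title Statistical tests used throughout the circuit analysis
#' @description Self-contained implementations of the two-proportion
#'   Z-test, Mann-Whitney U test (exact small-sample distribution via the
#'   standard counting recursion, tie-corrected normal approximation
#'   otherwise), the Mann-Kendall trend test (exact tail for short
#'   sequences via the inversion-number distribution) and Fisher's
#'   combined-probability method. Each returns an object of class
#'   `mea_test` holding the statistic, the p-value, sidedness, sample
#'   sizes and a method label, so every reported p-value is auditable.
NULL

mea_test <- function(method, statistic, p_value, sided, n, m = NA_integer_,
                     note = NULL) {
  structure(list(method = method, statistic = statistic,
                 p_value = min(max(p_value, 0), 1),
                 sided = sided, n = n, m = m, note = note),
            class = "mea_test")
}

#' @export
print.mea_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, %s p = %.4g (n = %d%s)\n",
              x$method, x$statistic, x$sided, x$p_value, x$n,
              if (!is.na(x$m)) paste0(", m = ", x$m) else ""))
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Two-proportion Z-test (pooled)
#'
#' Tests equality of two binomial proportions with the pooled-variance
#' normal approximation: `Z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))`
#' where `p` pools both samples. Degenerate pooled proportions (0 or 1)
#' give p = 1 with a warning.
#'
#' @param x1,n1 successes and trials in sample 1.
#' @param x2,n2 successes and trials in sample 2.
#' @param sided "two.sided" (default), "greater" (p1 > p2) or "less".
#' @param pooled use the pooled variance (default TRUE; FALSE uses the
#'   unpooled estimate).
#' @return A `mea_test`.
#' @export
two_proportion_z <- function(x1, n1, x2, n2,
                             sided = c("two.sided", "greater", "less"),
                             pooled = TRUE) {
  sided <- match.arg(sided)
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp == 0 || pp == 1) {
    warning("degenerate pooled proportion (", pp, "): p set to 1")
    return(mea_test("two-proportion Z (pooled)", 0, 1, sided, n1, n2,
                    note = "degenerate"))
  }
  se <- if (pooled) sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
        else sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  z <- (p1 - p2) / se
  p <- switch(sided,
              two.sided = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  mea_test(sprintf("two-proportion Z (%s)",
                   if (pooled) "pooled" else "unpooled"), z, p, sided, n1, n2)
}

# exact null distribution of the Mann-Whitney U statistic for sample
# sizes (n, m) without ties: counts of subsets by U, computed with the
# Gaussian-binomial polynomial recursion and cached per (n, m).
.mwu_cache <- new.env(parent = emptyenv())

mwu_exact_counts <- function(n, m) {
  key <- paste(n, m)
  if (!is.null(.mwu_cache[[key]])) return(.mwu_cache[[key]])
  # product_{i=1..n} (1 - q^(m+i)) / (1 - q^i), coefficients of q^u
  umax <- n * m
  coef <- numeric(umax + 1L)
  coef[1L] <- 1
  for (i in seq_len(n)) {
    # multiply by (1 - q^(m+i))
    s <- m + i
    if (s <= umax) coef[(s + 1L):(umax + 1L)] <-
        coef[(s + 1L):(umax + 1L)] - coef[1L:(umax + 1L - s)]
    # divide by (1 - q^i): cumulative sum with stride i
    if (i <= umax) for (u in (i + 1L):(umax + 1L))
      coef[u] <- coef[u] + coef[u - i]
  }
  .mwu_cache[[key]] <- coef
  coef
}

#' Mann-Whitney U test
#'
#' U is computed from midranks. Without ties and with `n * m <= 400` the
#' p-value is exact, from the full null distribution of U; otherwise a
#' tie-corrected normal approximation with continuity correction is
#' used.
#'
#' @param a,b numeric samples.
#' @param sided "two.sided" (default), "greater" (a tends larger) or
#'   "less".
#' @param exact force (TRUE) or forbid (FALSE) the exact distribution;
#'   NULL (default) decides as above.
#' @return A `mea_test`; `statistic` is U for sample `a`.
#' @export
mann_whitney_u <- function(a, b, sided = c("two.sided", "greater", "less"),
                           exact = NULL) {
  sided <- match.arg(sided)
  n <- length(a); m <- length(b)
  if (n < 1L || m < 1L) stop("both samples must be non-empty")
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2  # U for sample a
  ties <- table(c(a, b))
  has_ties <- any(ties > 1L)
  use_exact <- if (is.null(exact)) !has_ties && n * m <= 400 else isTRUE(exact)
  if (use_exact && has_ties) {
    warning("ties present: falling back to the normal approximation")
    use_exact <- FALSE
  }
  if (use_exact) {
    cnt <- mwu_exact_counts(n, m)
    tot <- sum(cnt)
    p_le <- sum(cnt[seq_len(u + 1L)]) / tot
    p_ge <- sum(cnt[(u + 1L):length(cnt)]) / tot
    p <- switch(sided,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge,
                less = p_le)
    return(mea_test("Mann-Whitney U (exact)", u, p, sided, n, m))
  }
  N <- n + m
  mu <- n * m / 2
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- n * m / 12 * ((N + 1) - tie_term)
  if (v <= 0) return(mea_test("Mann-Whitney U (normal)", u, 1, sided, n, m,
                              note = "zero variance (all values tied)"))
  cc <- 0.5
  p <- switch(sided,
              two.sided = 2 * stats::pnorm((abs(u - mu) - cc) / sqrt(v),
                                           lower.tail = FALSE),
              greater = stats::pnorm((u - mu - cc) / sqrt(v),
                                     lower.tail = FALSE),
              less = stats::pnorm((u - mu + cc) / sqrt(v)))
  mea_test("Mann-Whitney U (normal)", u, min(p, 1), sided, n, m)
}

# number of permutations of 1..n by inversion count (Mahonian numbers):
# coefficients of prod_{i=1..n-1} (1 + q + ... + q^i)
mk_inversion_counts <- function(n) {
  coef <- 1
  for (i in seq_len(n - 1L)) {
    new <- numeric(length(coef) + i)
    for (k in 0:i)
      new[(k + 1L):(k + length(coef))] <-
        new[(k + 1L):(k + length(coef))] + coef
    coef <- new
  }
  coef
}

#' Mann-Kendall trend test
#'
#' `S = sum_{i<j} sign(x[j] - x[i])`. For tie-free sequences of length
#' `n <= 10` the p-value is exact, from the permutation distribution of S
#' (via the inversion-number counts); otherwise the tie-corrected normal
#' approximation with continuity correction is used. Applied to a
#' sequence of group means across ordered sessions it is the "trend test
#' on means" used for developmental and dose-response trajectories.
#'
#' @param x ordered numeric sequence (length >= 3).
#' @param sided "two.sided" (default), "greater" (increasing trend) or
#'   "less" (decreasing trend).
#' @return A `mea_test`; `statistic` is S.
#' @export
mann_kendall <- function(x, sided = c("two.sided", "greater", "less")) {
  sided <- match.arg(sided)
  n <- length(x)
  if (n < 3L) stop("need a sequence of length >= 3")
  s <- 0L
  for (i in seq_len(n - 1L))
    s <- s + sum(sign(x[(i + 1L):n] - x[i]))
  ties <- table(x)
  has_ties <- any(ties > 1L)
  if (!has_ties && n <= 10L) {
    cnt <- mk_inversion_counts(n)  # inversions k; S = C(n,2) - 2k
    smax <- n * (n - 1) / 2
    s_vals <- smax - 2 * (seq_along(cnt) - 1L)
    tot <- sum(cnt)
    p_ge <- sum(cnt[s_vals >= s]) / tot
    p_le <- sum(cnt[s_vals <= s]) / tot
    p_abs <- sum(cnt[abs(s_vals) >= abs(s)]) / tot
    p <- switch(sided, two.sided = p_abs, greater = p_ge, less = p_le)
    return(mea_test("Mann-Kendall (exact)", s, p, sided, n))
  }
  v <- (n * (n - 1) * (2 * n + 5) -
          sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (v <= 0 || s == 0)
    return(mea_test("Mann-Kendall (normal)", s, 1, sided, n,
                    note = if (v <= 0) "no variance (all values tied)" else NULL))
  z <- (s - sign(s)) / sqrt(v)  # continuity correction
  p <- switch(sided,
              two.sided = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  mea_test("Mann-Kendall (normal)", s, min(p, 1), sided, n)
}

#' Fisher's combined probability method
#'
#' Combines k independent p-values via `X^2 = -2 sum(log(p))` with 2k
#' degrees of freedom.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return A `mea_test`; `statistic` is the chi-squared value.
#' @export
fishers_method <- function(p_values) {
  if (!length(p_values)) stop("no p-values to combine")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must be in [0, 1]")
  if (any(p_values == 0)) {
    warning("a combined p-value of 0 was supplied: combined p is 0")
    return(mea_test("Fisher's method", Inf, 0, "two.sided",
                    length(p_values)))
  }
  chisq <- -2 * sum(log(p_values))
  p <- stats::pchisq(chisq, df = 2 * length(p_values), lower.tail = FALSE)
  mea_test("Fisher's method", chisq, p, "two.sided", length(p_values))
}
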