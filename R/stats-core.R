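#' @keywords internal
test_result <- function(statistic, p_value, sidedness, method) {
  tibble::tibble(statistic = statistic,
                 p_value = min(max(p_value, 0), 1),
                 sidedness = sidedness,
                 method = method)
}

.sidedness <- c("two_sided", "one_sided_less", "one_sided_greater")

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, computed on
#' pairwise-complete observations (pairs missing in either vector are
#' dropped). The screens compared by this package score shRNA abundance
#' on different scales (normalized fold change vs shARP-style slopes),
#' so all between-screen concordance in the package is rank-based.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Spearman's rho in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) {
    stop("spearman_rho needs >= 3 complete pairs; got ", sum(ok), call. = FALSE)
  }
  stats::cor(x[ok], y[ok], method = "spearman")
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact p-value by the rank-sum null distribution when the combined
#' sample size is at most 12 and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections. The branch taken
#' is recorded in the `method` field.
#'
#' @param a,b Numeric vectors (NA dropped).
#' @param sidedness `"two_sided"`, `"one_sided_less"` (a shifted below
#'   b), or `"one_sided_greater"`.
#' @return One-row tibble: `statistic` (Mann-Whitney U for `a`),
#'   `p_value`, `sidedness`, `method`.
#' @examples
#' wilcoxon_rank_sum(1:3, 4:6)                 # p = 0.1
#' wilcoxon_rank_sum(1:3, 4:6, "one_sided_less")  # p = 0.05
#' @export
wilcoxon_rank_sum <- function(a, b, sidedness = .sidedness) {
  sidedness <- match.arg(sidedness)
  core <- ranksum_core(a[!is.na(a)], b[!is.na(b)], sidedness)
  test_result(core$statistic, core$p, sidedness, core$method)
}

# rank-sum p-value without result packaging; a, b must be NA-free
ranksum_core <- function(a, b, sidedness) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  if (n1 + n2 <= 12 && !ties) {
    p <- switch(sidedness,
      one_sided_less = stats::pwilcox(U, n1, n2),
      one_sided_greater = stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE),
      two_sided = {
        lo <- stats::pwilcox(U, n1, n2)
        hi <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
        min(1, 2 * min(lo, hi))
      })
    return(list(statistic = U, p = p, method = "wilcoxon_rank_sum_exact"))
  }
  n <- n1 + n2
  nties <- tabulate(match(r, unique(r)))
  sigma <- sqrt((n1 * n2 / 12) * ((n + 1) - sum(nties^3 - nties) / (n * (n - 1))))
  z <- U - n1 * n2 / 2
  if (sigma == 0) {
    return(list(statistic = U, p = 1, method = "wilcoxon_rank_sum_normal"))
  }
  corr <- switch(sidedness,
                 two_sided = sign(z) * 0.5,
                 one_sided_greater = 0.5,
                 one_sided_less = -0.5)
  zz <- (z - corr) / sigma
  p <- switch(sidedness,
              one_sided_less = stats::pnorm(zz),
              one_sided_greater = stats::pnorm(zz, lower.tail = FALSE),
              two_sided = min(1, 2 * min(stats::pnorm(zz),
                                         stats::pnorm(zz, lower.tail = FALSE))))
  list(statistic = U, p = min(1, max(0, p)), method = "wilcoxon_rank_sum_normal")
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are removed first. Exact sign-pattern p-value when
#' at most 12 non-zero differences remain and their magnitudes are
#' tie-free; otherwise the normal approximation with tie and continuity
#' corrections.
#'
#' @param d Numeric vector of paired differences (NA dropped).
#' @param sidedness `"two_sided"`, `"one_sided_less"` (differences
#'   shifted below 0), or `"one_sided_greater"`.
#' @return One-row tibble as in [wilcoxon_rank_sum()]; `statistic` is
#'   the positive-rank sum V.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3), "one_sided_greater")  # p = 0.125
#' @export
wilcoxon_signed_rank <- function(d, sidedness = .sidedness) {
  sidedness <- match.arg(sidedness)
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n < 1) stop("all paired differences are zero (degenerate input)", call. = FALSE)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 12 && !ties) {
    p <- switch(sidedness,
      one_sided_less = stats::psignrank(V, n),
      one_sided_greater = stats::psignrank(V - 1, n, lower.tail = FALSE),
      two_sided = {
        lo <- stats::psignrank(V, n)
        hi <- stats::psignrank(V - 1, n, lower.tail = FALSE)
        min(1, 2 * min(lo, hi))
      })
    return(test_result(V, p, sidedness, "wilcoxon_signed_rank_exact"))
  }
  nties <- table(r)
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(nties^3 - nties) / 48)
  z <- V - n * (n + 1) / 4
  if (sigma == 0) {
    return(test_result(V, 1, sidedness, "wilcoxon_signed_rank_normal"))
  }
  corr <- switch(sidedness,
                 two_sided = sign(z) * 0.5,
                 one_sided_greater = 0.5,
                 one_sided_less = -0.5)
  zz <- (z - corr) / sigma
  p <- switch(sidedness,
              one_sided_less = stats::pnorm(zz),
              one_sided_greater = stats::pnorm(zz, lower.tail = FALSE),
              two_sided = min(1, 2 * min(stats::pnorm(zz),
                                         stats::pnorm(zz, lower.tail = FALSE))))
  test_result(V, p, sidedness, "wilcoxon_signed_rank_normal")
}

#' Paired t-test
#'
#' Classic paired t statistic on `x - y` with n - 1 degrees of freedom.
#'
#' @param x,y Paired numeric vectors of equal length (pairs with NA
#'   dropped).
#' @param sidedness As in [wilcoxon_rank_sum()]; default two-sided.
#' @return One-row tibble: `statistic` is the t value.
#' @export
paired_t <- function(x, y, sidedness = .sidedness) {
  sidedness <- match.arg(sidedness)
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  d <- x[ok] - y[ok]
  n <- length(d)
  if (n < 3) stop("paired_t needs >= 3 complete pairs", call. = FALSE)
  s <- stats::sd(d)
  if (s == 0) stop("zero variance of paired differences", call. = FALSE)
  t <- mean(d) / (s / sqrt(n))
  p <- switch(sidedness,
              two_sided = 2 * stats::pt(-abs(t), n - 1),
              one_sided_greater = stats::pt(t, n - 1, lower.tail = FALSE),
              one_sided_less = stats::pt(t, n - 1))
  test_result(t, p, sidedness, "paired_t")
}

#' Shapiro-Wilk normality gate
#'
#' Returns TRUE when the Shapiro-Wilk test does not reject normality at
#' `alpha`. Used to choose between [paired_t()] and
#' [wilcoxon_signed_rank()] when comparing consistency reports.
#'
#' @param v Numeric vector, 3 <= length <= 5000 after NA removal.
#' @param alpha Significance level of the gate (default 0.05).
#' @return Logical scalar.
#' @export
normality_gate <- function(v, alpha = 0.05) {
  v <- v[!is.na(v)]
  if (length(v) < 3 || length(v) > 5000) {
    stop("normality_gate needs 3 <= n <= 5000; got ", length(v), call. = FALSE)
  }
  if (stats::sd(v) == 0) stop("constant vector: normality undefined", call. = FALSE)
  stats::shapiro.test(v)$p.value >= alpha
}
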