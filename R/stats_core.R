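# Statistical primitives shared by all pipeline stages. Tail probabilities
# are accumulated in log space so that enrichment p-values far below the
# double underflow threshold (the interesting regime for array-scale
# enrichments) are still reported exactly via log10_p.

#' Construct a tail-test result
#'
#' Container shared by all tests: `p_value` is `10^log10_p` whenever that is
#' representable, otherwise 0 with `log10_p` carrying the exact value.
#'
#' @param statistic Test statistic.
#' @param log10_p Base-10 log of the p-value (<= 0).
#' @param df Degrees of freedom, or NA.
#' @param method Label describing the test.
#' @param degenerate Flag set by tests that hit a degenerate input.
#' @return Object of class `tail_test`.
#' @export
tail_test <- function(statistic, log10_p, df = NA_real_, method = "",
                      degenerate = FALSE) {
  p <- 10^log10_p
  structure(list(statistic = statistic, p_value = p, log10_p = log10_p,
                 df = df, method = method, degenerate = degenerate),
            class = "tail_test")
}

#' @export
print.tail_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (log10 p = %.4g)%s\n",
              x$method, x$statistic, x$p_value, x$log10_p,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

# log(sum(exp(x))) without overflow; -Inf-safe
.logsumexp <- function(x) {
  x <- x[x > -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): draw `n` from a universe of `N`
#' containing `K` category members, observe `k` or more hits. Terms are
#' accumulated from log binomial coefficients so the log10 p-value is exact
#' even when the p-value itself underflows.
#'
#' @param N Universe size.
#' @param K Category size (0 <= K <= N).
#' @param n Draw size (0 <= n <= N).
#' @param k Observed hits; k <= 0 gives p = 1, k > min(K, n) gives p = 0.
#' @return A [tail_test()] with the upper-tail probability.
#' @export
hypergeometric_tail <- function(N, K, n, k) {
  if (any(c(N, K, n) < 0) || K > N || n > N)
    stop("require 0 <= K <= N and 0 <= n <= N")
  if (k <= 0)
    return(tail_test(k, 0, method = "hypergeometric upper tail"))
  if (k > min(K, n))
    return(tail_test(k, -Inf, method = "hypergeometric upper tail"))
  x <- seq.int(k, min(K, n))
  log_terms <- lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  log10_p <- min(.logsumexp(log_terms) / log(10), 0)
  tail_test(k, log10_p, method = "hypergeometric upper tail")
}

#' Binomial upper-tail probability in log space
#'
#' P(X >= k) for X ~ Binomial(n, p0), used for enrichment against a background
#' fraction when only the fraction (not a finite universe) is known. Stable for
#' p-values far below 1e-300.
#'
#' @param n Number of trials.
#' @param k Observed successes (0 <= k <= n).
#' @param p0 Background success probability in (0, 1).
#' @return A [tail_test()].
#' @export
log10_binomial_tail <- function(n, k, p0) {
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1)
    stop("p0 must be in (0, 1)")
  if (k < 0 || k > n)
    stop("require 0 <= k <= n")
  if (k <= 0)
    return(tail_test(k, 0, method = "binomial upper tail"))
  x <- seq.int(k, n)
  log_terms <- stats::dbinom(x, n, p0, log = TRUE)
  log10_p <- min(.logsumexp(log_terms) / log(10), 0)
  tail_test(k, log10_p, method = "binomial upper tail")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjustment: for p-values sorted ascending, q_(i) = min over j >= i
#' of m * p_(j) / j (capped at 1), mapped back to the input order. Ties are
#' broken by stable original index.
#'
#' @param p_values Numeric vector of p-values in \[0,1\].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must be in [0, 1]")
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(q)
  o <- order(pv)                       # stable: ties keep original index order
  adj <- pmin(1, rev(cummin(rev(pv[o] * m / seq_len(m)))))
  qv <- numeric(m)
  qv[o] <- adj
  q[ok] <- qv
  q
}

#' Welch two-sample t-test
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom, two-sided.
#' A variance floor (default 1e-12) is added to each group variance so that
#' constant groups do not divide by zero; results touching the floor are
#' flagged degenerate. Two constant groups with equal means give t = 0, p = 1.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param var_floor Variance floor added to each group variance.
#' @return A [tail_test()] with fields statistic (t), df and two-sided p.
#' @export
welch_t_test <- function(group_a, group_b, var_floor = 1e-12) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs >= 2 non-missing values")
  na <- length(a); nb <- length(b)
  va <- stats::var(a) + var_floor
  vb <- stats::var(b) + var_floor
  degenerate <- (stats::var(a) <= var_floor) || (stats::var(b) <= var_floor)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  log10_p <- min((log(2) + stats::pt(abs(t), df, lower.tail = FALSE,
                                     log.p = TRUE)) / log(10), 0)
  tail_test(t, log10_p, df = df, method = "Welch two-sample t (two-sided)",
            degenerate = degenerate)
}

#' Pooled-variance t-test from summary statistics
#'
#' Student two-sample t from printed (n, mean, SD) triplets, pooled variance,
#' df = n1 + n2 - 2, two-sided. Useful for re-testing published group
#' summaries such as immunohistochemistry scores.
#'
#' @param n1,mean1,sd1 First group: size (>= 2), mean, standard deviation.
#' @param n2,mean2,sd2 Second group.
#' @return A [tail_test()].
#' @export
pooled_t_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    if (mean1 == mean2)
      return(tail_test(0, 0, df = df, method = "pooled two-sample t (two-sided)",
                       degenerate = TRUE))
    return(tail_test(sign(mean1 - mean2) * Inf, -Inf, df = df,
                     method = "pooled two-sample t (two-sided)", degenerate = TRUE))
  }
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  log10_p <- min((log(2) + stats::pt(abs(t), df, lower.tail = FALSE,
                                     log.p = TRUE)) / log(10), 0)
  tail_test(t, log10_p, df = df, method = "pooled two-sample t (two-sided)")
}

#' Illumina-convention DiffScore
#'
#' 10 * sign(delta) * (-log10 p): |13| corresponds to p ~ 0.05 and |30| to
#' p = 0.001, matching the threshold semantics used on both the methylation
#' and expression platforms. A zero effect gives score 0.
#'
#' @param delta Signed effect (vectorized).
#' @param p_value p-value in (0, 1\] (vectorized).
#' @return Signed score, same length as the longer input.
#' @export
diff_score <- function(delta, p_value) {
  if (any(!is.finite(p_value) | p_value <= 0 | p_value > 1, na.rm = FALSE))
    stop("p_value must be in (0, 1]")
  10 * sign(delta) * (-log10(p_value))
}

#' Immunohistochemistry total score
#'
#' Combines a staining intensity score (0-3) and a stained-cell proportion
#' score (0-7) additively into a total score in 0-10.
#'
#' @param intensity Integer in 0..3.
#' @param proportion Integer in 0..7.
#' @return Integer total score.
#' @export
ihc_total_score <- function(intensity, proportion) {
  if (any(intensity != as.integer(intensity)) ||
      any(intensity < 0 | intensity > 3))
    stop("intensity must be an integer in 0..3")
  if (any(proportion != as.integer(proportion)) ||
      any(proportion < 0 | proportion > 7))
    stop("proportion must be an integer in 0..7")
  as.integer(intensity + proportion)
}
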