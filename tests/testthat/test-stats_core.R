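# exact-rational upper tail by direct binomial-coefficient arithmetic,
# independent of the log-gamma accumulation in the implementation
hyper_tail_oracle <- function(N, K, n, k) {
  if (k <= 0) return(1)
  hi <- min(K, n)
  if (k > hi) return(0)
  x <- k:hi
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

test_that("hypergeometric_tail matches exhaustive enumeration of draws", {
  # all C(10,4) = 210 draws from a universe with 5 category members
  hits <- combn(10, 4, function(s) sum(s <= 5))
  expect_equal(hypergeometric_tail(10, 5, 4, 4)$p_value, mean(hits >= 4))
  expect_equal(hypergeometric_tail(10, 5, 4, 4)$p_value, 5 / 210)
  expect_equal(hypergeometric_tail(10, 5, 4, 2)$p_value, mean(hits >= 2))
})

test_that("hypergeometric_tail agrees with coefficient arithmetic for N <= 25", {
  for (N in c(7L, 13L, 25L)) {
    for (K in 0:N) for (n in c(0L, 1L, N %/% 3, N %/% 2, N)) {
      for (k in 0:min(K, n)) {
        expected <- hyper_tail_oracle(N, K, n, k)
        got <- hypergeometric_tail(N, K, n, k)$p_value
        if (expected > 0) expect_lt(abs(got - expected) / expected, 1e-10)
        else expect_identical(got, 0)
      }
    }
  }
})

test_that("hypergeometric_tail handles boundary k and bad parameters", {
  expect_equal(hypergeometric_tail(100, 10, 10, 0)$p_value, 1)
  expect_equal(hypergeometric_tail(100, 10, 10, -3)$p_value, 1)
  expect_equal(hypergeometric_tail(100, 10, 10, 11)$p_value, 0)
  expect_equal(hypergeometric_tail(20, 6, 5, 2)$p_value, 0.4834881, tolerance = 1e-6)
  expect_error(hypergeometric_tail(10, 12, 5, 1), "K <= N")
  expect_error(hypergeometric_tail(10, 5, 12, 1), "n <= N")
})

test_that("hypergeometric log10_p stays exact deep in the tail", {
  # cross-check against phyper computed fully in log space
  cases <- list(c(20000, 4200, 300, 141), c(450000, 94500, 2961, 1395))
  for (cs in cases) {
    got <- hypergeometric_tail(cs[1], cs[2], cs[3], cs[4])$log10_p
    ref <- phyper(cs[4] - 1, cs[2], cs[1] - cs[2], cs[3],
                  lower.tail = FALSE, log.p = TRUE) / log(10)
    expect_equal(got, ref, tolerance = 1e-8)
  }
})

test_that("log10_binomial_tail is exact, monotone and KL-bounded", {
  expect_equal(log10_binomial_tail(10, 0, 0.21)$p_value, 1)
  expect_equal(log10_binomial_tail(4, 4, 0.5)$p_value, 0.0625)
  # deep tail: exact log-space value, verified against pbinom in log space
  got <- log10_binomial_tail(2961, 1395, 0.21)$log10_p
  ref <- pbinom(1394, 2961, 0.21, lower.tail = FALSE, log.p = TRUE) / log(10)
  expect_equal(got, ref, tolerance = 1e-8)
  expect_equal(got, -218.2953, tolerance = 1e-3)
  # KL (Chernoff) upper bound for k/n > p0
  n <- 2961; k <- 1395; p0 <- 0.21; q <- k / n
  kl <- q * log(q / p0) + (1 - q) * log((1 - q) / (1 - p0))
  expect_lte(got, -n * kl / log(10))
  # monotone non-increasing in k
  lp <- vapply(0:50, function(k) log10_binomial_tail(50, k, 0.3)$log10_p, 0)
  expect_true(all(diff(lp) <= 1e-12))
  expect_error(log10_binomial_tail(10, 2, 1.2), "p0")
  expect_error(log10_binomial_tail(10, 12, 0.5), "k <= n")
})

test_that("bh_fdr implements the step-up rule", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # brute-force oracle: q_i = min over j with p_j >= p_i of m * p_j / rank_j
  bh_oracle <- function(p) {
    m <- length(p)
    r <- rank(p, ties.method = "max")
    vapply(seq_len(m),
           function(i) min(1, min((m * p / r)[p >= p[i]])), numeric(1))
  }
  set.seed(42)
  for (rep in 1:20) {
    p <- round(runif(sample(1:40, 1)), 3)
    q <- bh_fdr(p)
    expect_equal(q, p.adjust(p, method = "BH"))
    expect_equal(q, bh_oracle(p))
    # monotone: sorting by p gives non-decreasing q
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    expect_true(all(q <= 1))
    expect_gte(q[which.min(p)], min(p))
  }
  expect_error(bh_fdr(c(0.5, 1.4)), "\\[0, 1\\]")
  expect_equal(bh_fdr(c(0.2, NA, 0.01)), c(p.adjust(c(0.2, 0.01), "BH")[1], NA,
                                           p.adjust(c(0.2, 0.01), "BH")[2]))
})

test_that("welch_t_test matches hand evaluation and t.test", {
  r <- welch_t_test(c(1.1, 0.9, 1.0), c(2.1, 1.9, 2.0))
  expect_equal(r$statistic, -12.24745, tolerance = 1e-6)
  expect_equal(r$df, 4, tolerance = 1e-6)
  expect_equal(r$p_value, 2.552167e-4, tolerance = 1e-6)
  tt <- t.test(c(0.3, 1.2, 0.8, 2.0), c(1.4, 0.2, 2.2))
  r2 <- welch_t_test(c(0.3, 1.2, 0.8, 2.0), c(1.4, 0.2, 2.2))
  expect_equal(r2$statistic, unname(tt$statistic), tolerance = 1e-8)
  expect_equal(r2$p_value, tt$p.value, tolerance = 1e-8)
})

test_that("welch_t_test handles identical and degenerate groups", {
  r <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$degenerate)
  d <- welch_t_test(c(0, 0, 0, 0), c(10, 10, 10, 10))
  expect_true(d$degenerate)
  expect_lt(d$p_value, 1e-10)
  z <- welch_t_test(c(5, 5), c(5, 5))
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
  expect_error(welch_t_test(1, c(1, 2)), ">= 2")
})

test_that("welch_t_test is antisymmetric under group swap", {
  set.seed(11)
  for (i in 1:10) {
    a <- rnorm(sample(2:6, 1)); b <- rnorm(sample(2:6, 1), mean = 0.5)
    r1 <- welch_t_test(a, b); r2 <- welch_t_test(b, a)
    expect_equal(r1$statistic, -r2$statistic)
    expect_equal(r1$p_value, r2$p_value)
    expect_equal(r1$df, r2$df)
  }
})

test_that("pooled_t_from_summary reproduces published-style summaries", {
  r0 <- pooled_t_from_summary(8, 5.0, 1.0, 8, 5.0, 1.0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  r1 <- pooled_t_from_summary(3, 0, 0, 56, 4.2, 3)
  expect_equal(r1$statistic, -2.404987, tolerance = 1e-6)
  expect_equal(r1$df, 57)
  expect_equal(r1$p_value, 0.019443, tolerance = 1e-4)
  r2 <- pooled_t_from_summary(13, 5.7, 1.8, 39, 7.9, 2.4)
  expect_equal(r2$statistic, -3.025535, tolerance = 1e-6)
  expect_equal(r2$df, 50)
  # degenerate: zero pooled variance
  expect_true(pooled_t_from_summary(3, 1, 0, 3, 1, 0)$degenerate)
  expect_equal(pooled_t_from_summary(3, 1, 0, 3, 1, 0)$p_value, 1)
  expect_equal(pooled_t_from_summary(3, 1, 0, 3, 2, 0)$p_value, 0)
  expect_error(pooled_t_from_summary(1, 0, 1, 5, 0, 1), ">= 2")
  expect_error(pooled_t_from_summary(3, 0, -1, 5, 0, 1), ">= 0")
})

test_that("diff_score follows the 10 * sign * (-log10 p) convention", {
  expect_equal(diff_score(1, 0.05), 13.0103, tolerance = 1e-4)
  expect_equal(diff_score(-2, 0.001), -30)
  expect_equal(diff_score(0.7, 1), 0)
  expect_equal(diff_score(0, 0.01), 0)
  # crosses +/-13 exactly at p = 10^(-1.3)
  expect_equal(abs(diff_score(1, 10^(-1.3))), 13)
  expect_lt(abs(diff_score(1, 10^(-1.3) * 1.001)), 13)
  expect_gt(abs(diff_score(1, 10^(-1.3) / 1.001)), 13)
  expect_error(diff_score(1, 0), "p_value")
  expect_error(diff_score(1, -0.5), "p_value")
})

test_that("ihc_total_score adds intensity and proportion", {
  expect_identical(ihc_total_score(3, 7), 10L)
  expect_identical(ihc_total_score(0, 0), 0L)
  expect_identical(ihc_total_score(2, 5), 7L)
  expect_error(ihc_total_score(4, 5), "0..3")
  expect_error(ihc_total_score(2, 8), "0..7")
})

test_that("tail_test keeps p and log10_p consistent under underflow", {
  r <- hypergeometric_tail(20000, 4200, 300, 141)
  expect_equal(r$p_value, 10^r$log10_p)
  deep <- log10_binomial_tail(5000, 4000, 0.1)
  expect_identical(deep$p_value, 0)            # underflows double precision
  expect_lt(deep$log10_p, -1000)
  expect_true(is.finite(deep$log10_p))
})
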