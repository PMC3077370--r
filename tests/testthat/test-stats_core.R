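# Exact 2x2 machinery and the generic tests.

test_that("hypergeometric tail matches enumeration on the worked examples", {
  # N=10, m=5, n=5, k=5: only one of the C(10,5)=252 draws overlaps fully
  expect_equal(hypergeom_tail(contingency_2x2(5, 0, 0, 5), "greater"),
               1 / 252, tolerance = 1e-12)
  # k = 0: the greater tail covers every outcome
  expect_equal(hypergeom_tail(contingency_2x2(0, 4, 6, 3), "greater"), 1)
  # N=8, m=4, n=4, k=3
  expect_equal(hypergeom_tail(contingency_2x2(3, 1, 1, 3), "greater"),
               17 / 70, tolerance = 1e-12)
  # cross-check the stable log-gamma path against phyper on larger counts
  tb <- contingency_2x2(40, 160, 60, 740)
  expect_equal(hypergeom_tail(tb, "greater"),
               phyper(39, 100, 900, 200, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("greater and less tails partition the probability mass", {
  set.seed(42)
  for (rep in 1:25) {
    N <- sample(5:60, 1); m <- sample(1:(N - 1), 1); n <- sample(1:(N - 1), 1)
    lo <- max(0, n - (N - m)); hi <- min(m, n)
    if (hi <= lo) next
    ks <- (lo + 1):hi
    k <- ks[sample.int(length(ks), 1)]
    a <- k; b <- n - k; c <- m - k; d <- (N - m) - (n - k)
    pg <- hypergeom_tail(contingency_2x2(a, b, c, d), "greater")
    pl <- hypergeom_tail(contingency_2x2(a - 1, b + 1, c + 1, d - 1), "less")
    expect_equal(pg + pl, 1, tolerance = 1e-10)
  }
})

test_that("Fisher's exact test follows the pmf-ordering rule", {
  r <- fisher_exact_2x2(contingency_2x2(5, 5, 5, 5))
  expect_equal(r$effect, 1)
  expect_equal(r$p_value, 1)

  r2 <- fisher_exact_2x2(contingency_2x2(8, 2, 2, 8))
  expect_equal(r2$p_value, oracle_fisher_two_sided(20, 10, 10, 8),
               tolerance = 1e-12)
  expect_equal(r2$p_value,
               fisher.test(matrix(c(8, 2, 2, 8), 2))$p.value,
               tolerance = 1e-09)

  # extreme depletion: OR 0, Haldane-corrected CI, one-sided less tail
  r3 <- fisher_exact_2x2(contingency_2x2(0, 10, 10, 0))
  expect_equal(r3$effect, 0)
  expect_true(is.finite(r3$ci_lower) && is.finite(r3$ci_upper))
  r3l <- fisher_exact_2x2(contingency_2x2(0, 10, 10, 0), tail = "less")
  expect_equal(r3l$p_value,
               hypergeom_tail(contingency_2x2(0, 10, 10, 0), "less"))

  # zero margin: p = 1, effect missing, no error
  r4 <- fisher_exact_2x2(contingency_2x2(0, 0, 5, 7))
  expect_equal(r4$p_value, 1)
  expect_true(is.na(r4$effect))
})

test_that("two-sided Fisher p brackets the observed-direction one-sided p", {
  # the two-sided pmf-ordering p always contains the smaller tail and never
  # exceeds the sum of both tails
  set.seed(7)
  for (rep in 1:20) {
    cells <- sample(0:12, 4, replace = TRUE)
    if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0) next
    tb <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    p2 <- fisher_exact_2x2(tb, "two_sided")$p_value
    pg <- fisher_exact_2x2(tb, "greater")$p_value
    pl <- fisher_exact_2x2(tb, "less")$p_value
    expect_gte(p2 + 1e-12, min(pg, pl))
    expect_lte(p2, pg + pl + 1e-12)
    expect_true(all(c(p2, pg, pl) >= 0 & c(p2, pg, pl) <= 1))
  }
})

test_that("Wilcoxon rank-sum: exact small-sample path and tie handling", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)       # 2/20 rank assignments as extreme
  expect_match(r$method, "exact")

  # identical multisets carry ties, so the tie-corrected path yields p = 1
  r2 <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$p_value, 1)
  expect_error(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3), mode = "exact"),
               "tie")
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("exact Wilcoxon agrees with Monte-Carlo permutation on small instances", {
  set.seed(11)
  for (rep in 1:10) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    vals <- sample(1:100, n1 + n2)   # tie-free
    x <- vals[1:n1]; y <- vals[-(1:n1)]
    p_exact <- wilcoxon_rank_sum(x, y, mode = "exact")$p_value
    B <- 20000
    w_obs <- sum(rank(c(x, y))[1:n1]) - n1 * (n1 + 1) / 2
    e_w <- n1 * n2 / 2
    w_perm <- replicate(B, {
      idx <- sample(n1 + n2, n1)
      sum(rank(vals)[idx]) - n1 * (n1 + 1) / 2
    })
    p_mc <- mean(abs(w_perm - e_w) >= abs(w_obs - e_w) - 1e-9)
    se <- sqrt(p_mc * (1 - p_mc) / B)
    expect_lt(abs(p_exact - p_mc), 3 * se + 1e-6)
  }
})

test_that("large location shifts give vanishing normal-approximation p", {
  set.seed(3)
  x <- rnorm(200); y <- rnorm(200) + 1
  expect_lt(wilcoxon_rank_sum(y, x, mode = "normal_approx")$p_value, 1e-15)
})

test_that("bootstrap median SE: degenerate, reproducible, calibrated", {
  expect_equal(bootstrap_median_se(rep(2.5, 40), B = 200, seed = 1), 0)
  v0 <- rnorm(50)
  expect_identical(bootstrap_median_se(v0, B = 300, seed = 9),
                   bootstrap_median_se(v0, B = 300, seed = 9))
  set.seed(5)
  v <- rnorm(400)
  se <- bootstrap_median_se(v, B = 2000, seed = 2)
  asymp <- 1.2533 / sqrt(400)        # sqrt(pi/2)/sqrt(n) for the median
  expect_lt(abs(se - asymp) / asymp, 0.25)
})

test_that("Welch t and KS comparisons behave as documented", {
  x <- c(1, 2, 3, 4, 5)
  r <- distribution_compare(x, x, mode = "welch_t")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  y <- c(2.5, 3.1, 4.7, 5.2, 6.6, 7.0, 8.3)
  r2 <- distribution_compare(x, y, mode = "welch_t")
  # direct formula evaluation
  se <- sqrt(var(x) / 5 + var(y) / 7)
  tval <- (mean(x) - mean(y)) / se
  df <- se^4 / ((var(x) / 5)^2 / 4 + (var(y) / 7)^2 / 6)
  expect_equal(r2$statistic, tval, tolerance = 1e-12)
  expect_equal(r2$p_value, 2 * pt(-abs(tval), df), tolerance = 1e-12)

  # exact normal quantiles against the fitted normal: no detectable misfit
  q <- qnorm(ppoints(200), mean = 4.2, sd = 0.7)
  r3 <- distribution_compare(q, mode = "ks")
  expect_gt(r3$p_value, 0.5)
})

test_that("test results serialize and validate", {
  r <- fisher_exact_2x2(contingency_2x2(3, 1, 2, 4))
  df <- as.data.frame(r)
  expect_true(all(c("statistic", "p_value", "effect") %in% names(df)))
  expect_error(test_result(p_value = 1.5), "p_value")
  expect_error(contingency_2x2(-1, 2, 3, 4), "non-negative")
})
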