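# Exact 2x2 machinery used throughout: the hypergeometric tail sum behind the
# motif-threshold contingency test, Fisher's exact test with a pmf-ordering
# two-sided rule, and the generic location/distribution tests.

#' Construct a 2x2 contingency table
#'
#' Cell layout follows the threshold-selection table: `a` counts sequences
#' that are both in the positive class (5UI-) and motif-containing, `b` the
#' motif-containing 5UI+ sequences, `c` the non-matching 5UI- sequences and
#' `d` the non-matching 5UI+ sequences. Derived margins are `N = a+b+c+d`,
#' `m = a+c` (positive-class total), `n = a+b` (motif-containing total) and
#' `k = a` (the overlap).
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return An object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("cell counts must be non-negative integers")
  structure(list(a = a, b = b, c = c, d = d,
                 N = a + b + c + d, m = a + c, n = a + b, k = a),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("match", "no match"), c("pos", "neg")))
  print(m)
  invisible(x)
}

.as_table2x2 <- function(table) {
  if (inherits(table, "contingency_2x2")) return(table)
  if (is.matrix(table) && all(dim(table) == c(2L, 2L)))
    return(contingency_2x2(table[1, 1], table[1, 2], table[2, 1], table[2, 2]))
  if (is.numeric(table) && length(table) == 4L)
    return(contingency_2x2(table[1], table[2], table[3], table[4]))
  stop("expected a contingency_2x2, a 2x2 matrix, or a length-4 numeric")
}

# log hypergeometric pmf: probability of i overlaps out of n draws from a
# population of N with m positives.
.hyper_lpmf <- function(i, N, m, n) {
  lchoose(m, i) + lchoose(N - m, n - i) - lchoose(N, n)
}

.logsumexp <- function(lx) {
  lx <- lx[is.finite(lx)]
  if (!length(lx)) return(-Inf)
  mx <- max(lx)
  mx + log(sum(exp(lx - mx)))
}

#' Exact hypergeometric tail probability
#'
#' Computes the tail sum of the hypergeometric distribution for a 2x2 table:
#' with `greater`, the probability of observing `k` or more overlaps between
#' the positive class (margin `m`) and the matching class (margin `n`) in a
#' population of `N`; with `less`, the probability of `k` or fewer. The sum
#' is evaluated in log-gamma arithmetic for numerical stability.
#'
#' @param table A [contingency_2x2()] (or 2x2 matrix / length-4 vector).
#' @param tail `"greater"` or `"less"`.
#' @return The exact tail probability.
#' @export
hypergeom_tail <- function(table, tail = c("greater", "less")) {
  tail <- match.arg(tail)
  tb <- .as_table2x2(table)
  N <- tb$N; m <- tb$m; n <- tb$n; k <- tb$k
  lo <- max(0L, n - (N - m))
  hi <- min(m, n)
  if (k < lo || k > hi) stop("inconsistent margins")
  idx <- if (tail == "greater") seq(k, hi) else seq(lo, k)
  p <- exp(.logsumexp(.hyper_lpmf(idx, N, m, n)))
  min(max(p, 0), 1)
}

# Two-sided Fisher p-values for every attainable overlap k at fixed margins.
# Returns a named numeric vector over k = lo..hi. Used by fisher_exact_2x2
# and, in bulk, by the permutation machinery in the enrichment module.
.fisher_two_sided_profile <- function(N, m, n) {
  lo <- max(0L, n - (N - m))
  hi <- min(m, n)
  supp <- seq(lo, hi)
  lp <- .hyper_lpmf(supp, N, m, n)
  pr <- exp(lp - .logsumexp(lp))  # renormalize to kill rounding drift
  # two-sided rule: sum probabilities of tables no more likely than observed
  tol <- log1p(1e-07)
  p <- vapply(seq_along(supp),
              function(j) sum(pr[lp <= lp[j] + tol]), numeric(1))
  stats::setNames(pmin(p, 1), supp)
}

#' Container for a test outcome
#'
#' @param statistic Test statistic.
#' @param p_value P-value in `[0, 1]`.
#' @param effect Effect estimate (odds ratio or location shift).
#' @param ci_lower,ci_upper 95% confidence bounds for `effect`.
#' @param tail One of `"greater"`, `"less"`, `"two_sided"`.
#' @param method Free-text description.
#' @return An object of class `alrex_test`.
#' @export
test_result <- function(statistic = NA_real_, p_value = NA_real_,
                        effect = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, tail = "two_sided",
                        method = "") {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(list(statistic = statistic, p_value = p_value, effect = effect,
                 ci_lower = ci_lower, ci_upper = ci_upper, tail = tail,
                 method = method),
            class = "alrex_test")
}

#' @export
print.alrex_test <- function(x, ...) {
  cat(x$method, "\n", sep = "")
  cat(sprintf("  statistic = %.6g, p (%s) = %.4g\n",
              x$statistic, x$tail, x$p_value))
  if (!is.na(x$effect))
    cat(sprintf("  effect = %.4g [%.4g, %.4g]\n",
                x$effect, x$ci_lower, x$ci_upper))
  invisible(x)
}

#' @method as.data.frame alrex_test
#' @export
as.data.frame.alrex_test <- function(x, ...) {
  data.frame(statistic = x$statistic, p_value = x$p_value, effect = x$effect,
             ci_lower = x$ci_lower, ci_upper = x$ci_upper, tail = x$tail,
             method = x$method, stringsAsFactors = FALSE)
}

#' Fisher's exact test for a 2x2 table
#'
#' One-sided p-values are hypergeometric tail sums ([hypergeom_tail()]); the
#' two-sided p-value sums the probabilities of all tables with the observed
#' margins whose pmf does not exceed the observed one (the convention of
#' mainstream statistical software). The effect is the sample odds ratio
#' `ad/bc`; its 95% CI is the Woolf log-OR interval, with a Haldane +0.5
#' correction applied only when some cell is zero. A zero margin gives
#' p = 1 with a missing effect rather than an error.
#'
#' @inheritParams hypergeom_tail
#' @param tail `"two_sided"`, `"greater"` or `"less"`.
#' @return An [test_result()] with the odds ratio as effect.
#' @export
fisher_exact_2x2 <- function(table, tail = c("two_sided", "greater", "less")) {
  tail <- match.arg(tail)
  tb <- .as_table2x2(table)
  a <- tb$a; b <- tb$b; c <- tb$c; d <- tb$d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0))
    return(test_result(statistic = tb$k, p_value = 1, effect = NA_real_,
                       tail = tail, method = "Fisher's exact test (degenerate margin)"))
  p <- if (tail == "two_sided") {
    prof <- .fisher_two_sided_profile(tb$N, tb$m, tb$n)
    unname(prof[as.character(tb$k)])
  } else {
    hypergeom_tail(tb, tail)
  }
  or <- (a * d) / (b * c)
  cells <- c(a, b, c, d)
  if (any(cells == 0)) cells <- cells + 0.5  # Haldane, zero cells only
  or_ci <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  test_result(statistic = tb$k, p_value = min(p, 1), effect = or,
              ci_lower = exp(log(or_ci) - 1.959964 * se),
              ci_upper = exp(log(or_ci) + 1.959964 * se),
              tail = tail, method = "Fisher's exact test")
}

#' Wilcoxon rank-sum test
#'
#' Exact two-sided enumeration when the pooled sample is small (`n + m <= 12`)
#' and tie-free; otherwise the normal approximation with midranks, tie
#' variance correction and continuity correction. Requesting `mode = "exact"`
#' on tied data is an error.
#'
#' @param x,y Non-empty numeric samples.
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @param tail Alternative: `"two_sided"`, `"greater"` (x shifted up), `"less"`.
#' @return An [test_result()]; effect is the difference of sample medians.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal_approx"),
                              tail = c("two_sided", "greater", "less")) {
  mode <- match.arg(mode)
  tail <- match.arg(tail)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- switch(mode,
    auto = (length(x) + length(y) <= 12L) && !ties,
    exact = TRUE,
    normal_approx = FALSE)
  if (mode == "exact" && ties)
    stop("exact Wilcoxon requires tie-free data; use normal_approx")
  alt <- switch(tail, two_sided = "two.sided", greater = "greater", less = "less")
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alt, exact = use_exact,
                       correct = TRUE))
  test_result(statistic = unname(wt$statistic), p_value = wt$p.value,
              effect = stats::median(x) - stats::median(y), tail = tail,
              method = paste0("Wilcoxon rank-sum (",
                              if (use_exact) "exact" else "normal approx", ")"))
}

#' Bootstrap standard error of the median
#'
#' @param values Non-empty numeric vector.
#' @param B Number of resamples (at least 100).
#' @param seed Integer seed; resampling is deterministic given the seed.
#' @return Standard deviation of the `B` resampled medians.
#' @export
bootstrap_median_se <- function(values, B = 1000L, seed = 1L) {
  stopifnot(length(values) >= 1L, B >= 100L)
  meds <- withr::with_seed(seed, {
    vapply(seq_len(B),
           function(i) stats::median(sample(values, replace = TRUE)),
           numeric(1))
  })
  stats::sd(meds)
}

#' Distributional comparisons: Welch t and Kolmogorov-Smirnov
#'
#' `welch_t` compares two samples with unequal-variance t and Satterthwaite
#' degrees of freedom. `ks` compares two samples when `y` is given, or one
#' sample against a normal with mean and sd estimated from the data when
#' `reference = "normal"` (note the estimated-parameter caveat: the nominal
#' p-value is conservative only in the classical sense and is used here the
#' way goodness-of-fit panels commonly use it).
#'
#' @param x Numeric sample (length >= 3).
#' @param y Optional second sample.
#' @param reference Reference distribution for one-sample KS (`"normal"`).
#' @param mode `"welch_t"` or `"ks"`.
#' @return An [test_result()].
#' @export
distribution_compare <- function(x, y = NULL, reference = "normal",
                                 mode = c("welch_t", "ks")) {
  mode <- match.arg(mode)
  if (length(x) < 3L) stop("need at least 3 observations")
  if (mode == "welch_t") {
    if (is.null(y)) stop("welch_t requires two samples")
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (isTRUE(all.equal(mean(x), mean(y))))
        return(test_result(statistic = 0, p_value = 1, effect = 0,
                           method = "Welch two-sample t (degenerate: zero variance)"))
      stop("zero variance in both samples")
    }
    tt <- stats::t.test(x, y, var.equal = FALSE)
    return(test_result(statistic = unname(tt$statistic), p_value = tt$p.value,
                       effect = unname(diff(rev(tt$estimate))),
                       ci_lower = tt$conf.int[1], ci_upper = tt$conf.int[2],
                       method = sprintf("Welch two-sample t (df = %.2f)",
                                        unname(tt$parameter))))
  }
  kt <- if (!is.null(y)) {
    suppressWarnings(stats::ks.test(x, y))
  } else {
    if (!identical(reference, "normal"))
      stop("only the normal reference is supported")
    suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  }
  test_result(statistic = unname(kt$statistic), p_value = kt$p.value,
              method = kt$method)
}
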