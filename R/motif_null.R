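# Dirichlet random-PSSM null model: random motifs whose columns are
# Dirichlet draws with concentration equal to the background base
# frequencies (total concentration 1, hence sparse, peaked columns), ROC
# curves under the motif-containing classification rule, percentile ranking
# of a target motif against the null ensemble, and the t' threshold that
# maximizes the TPR gap over the null median at matched FPR.

#' Empirical background of the first bases of a sequence pool
#'
#' @param seqs Character vector of sequences.
#' @param region Number of leading nt per sequence to pool (default 99).
#' @return Named length-4 frequency vector over A/C/G/T.
#' @export
sequence_background <- function(seqs, region = 99L) {
  pooled <- paste(substr(seqs, 1, region), collapse = "")
  counts <- vapply(c("A", "C", "G", "T"), function(b)
    nchar(gsub(paste0("[^", b, "]"), "", pooled)), numeric(1))
  counts / sum(counts)
}

.rdirichlet_cols <- function(n_cols, alpha) {
  g <- matrix(stats::rgamma(4L * n_cols, shape = alpha), nrow = 4L)
  zero <- colSums(g) == 0
  while (any(zero)) {  # guard against total underflow at tiny concentrations
    g[, zero] <- stats::rgamma(4L * sum(zero), shape = alpha)
    zero <- colSums(g) == 0
  }
  sweep(pmax(g, 1e-300), 2, colSums(g), "/")
}

#' Sample a random PSSM from the Dirichlet null
#'
#' Each column is an independent Dirichlet draw with concentration vector
#' equal to the background frequencies (so the total concentration is 1 and
#' the expected column equals the background).
#'
#' @param length Motif width (>= 4).
#' @param background Length-4 positive frequency vector summing to 1.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A [new_pssm()] object.
#' @export
sample_random_pssm <- function(length, background = rep(0.25, 4), seed = 1L) {
  if (abs(sum(background) - 1) > 1e-09 || any(background <= 0))
    stop("background must be positive and sum to 1")
  probs <- withr::with_seed(seed, .rdirichlet_cols(length, background))
  probs <- sweep(probs, 2, colSums(probs), "/")
  new_pssm(probs, background = background, name = paste0("null_", seed))
}

# Draw a list of null PSSMs inside a single seeded stream.
.sample_null_pssms <- function(n_null, length, background, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n_null), function(i) {
      probs <- .rdirichlet_cols(length, background)
      probs <- sweep(probs, 2, colSums(probs), "/")
      new_pssm(probs, background = background, name = paste0("null_", i))
    })
  })
}

#' Build an ROC curve from per-sequence maximum scores
#'
#' Sequences are classified motif-containing when their maximum score is
#' `>= t`. Thresholds sweep the union of observed maxima in descending
#' order, with a `+Inf` sentinel so the curve includes (0, 0); at the lowest
#' observed score the curve reaches (1, 1). TPR is the motif-containing
#' fraction of the positive (5UI-) set; FPR the same for the negative (5UI+)
#' set.
#'
#' @param max_scores_pos,max_scores_neg Per-sequence maximum scores.
#' @return Object of class `roc_curve` with `thresholds`, `tpr`, `fpr`.
#' @export
build_roc <- function(max_scores_pos, max_scores_neg) {
  if (!length(max_scores_pos) || !length(max_scores_neg))
    stop("both score lists must be non-empty")
  thr <- c(Inf, sort(unique(c(max_scores_pos, max_scores_neg)),
                     decreasing = TRUE))
  sp <- sort(max_scores_pos); sn <- sort(max_scores_neg)
  n_pos <- length(sp); n_neg <- length(sn)
  tpr <- (n_pos - findInterval(thr, sp, left.open = TRUE)) / n_pos
  fpr <- (n_neg - findInterval(thr, sn, left.open = TRUE)) / n_neg
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr),
            class = "roc_curve")
}

#' Area under an ROC curve (trapezoid)
#'
#' @param roc A [build_roc()] curve.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

#' TPR of a curve at a grid FPR (step interpolation)
#'
#' Returns the TPR at the smallest threshold whose FPR does not exceed the
#' grid value -- i.e. the largest achievable TPR subject to `FPR <= g`.
#'
#' @param roc A [build_roc()] curve.
#' @param fpr Grid FPR value(s) in `[0, 1]`.
#' @return Numeric vector of TPR values.
#' @export
roc_tpr_at_fpr <- function(roc, fpr) {
  vapply(fpr, function(g) {
    ok <- roc$fpr <= g
    if (!any(ok)) 0 else max(roc$tpr[ok])
  }, numeric(1))
}

#' Rank a target PSSM against the Dirichlet null ensemble
#'
#' Scans every sequence with the target and with `n_null` random PSSMs of
#' the same width (same threshold-free scanning machinery), builds each
#' motif's ROC for discriminating the positive (5UI-) from the negative
#' (5UI+) set, and evaluates TPR at each grid FPR by step interpolation. The
#' percentile at a grid point is the fraction of null motifs with TPR
#' strictly below the target's; `outperforms_q` summarizes the minimum
#' percentile over the grid.
#'
#' @param target A [new_pssm()] object.
#' @param pos_seqs,neg_seqs Sequences of the positive (5UI-) and negative
#'   (5UI+) sets.
#' @param n_null Number of null PSSMs (>= 100).
#' @param fpr_grid FPR grid in (0, 1).
#' @param seed Integer seed for the null draws.
#' @param region Scan region in nt.
#' @param background Background frequencies; defaults to the empirical
#'   composition of the pooled first-`region` nt of both sets.
#' @param keep_null_rocs Also return the per-null ROC curves (for t'
#'   selection or audit).
#' @return Object of class `null_ranking`: `fpr_grid`, `target_tpr`,
#'   `null_tpr_median`, `percentile`, `n_null`, `outperforms_q`, plus
#'   `target_roc` and optionally `null_rocs` / `null_tpr` matrix.
#' @export
rank_against_null <- function(target, pos_seqs, neg_seqs, n_null = 1000L,
                              fpr_grid = seq(0.1, 0.7, by = 0.1), seed = 1L,
                              region = 99L, background = NULL,
                              keep_null_rocs = FALSE) {
  if (n_null < 100L) stop("n_null must be at least 100")
  if (any(fpr_grid <= 0 | fpr_grid >= 1)) stop("fpr_grid values must be in (0,1)")
  if (any(nchar(c(pos_seqs, neg_seqs)) < target$length))
    stop("sequence shorter than the target motif")
  if (is.null(background))
    background <- sequence_background(c(pos_seqs, neg_seqs), region)
  codes_pos <- .encode_region(pos_seqs, region)
  codes_neg <- .encode_region(neg_seqs, region)
  target_roc <- build_roc(pssm_max_scores(target, codes_pos),
                          pssm_max_scores(target, codes_neg))
  target_tpr <- roc_tpr_at_fpr(target_roc, fpr_grid)
  nulls <- .sample_null_pssms(n_null, target$length, background,
                              derive_seed(seed, 11L))
  null_tpr <- matrix(NA_real_, n_null, length(fpr_grid))
  null_rocs <- if (keep_null_rocs) vector("list", n_null) else NULL
  for (i in seq_len(n_null)) {
    roc_i <- build_roc(pssm_max_scores(nulls[[i]], codes_pos),
                       pssm_max_scores(nulls[[i]], codes_neg))
    null_tpr[i, ] <- roc_tpr_at_fpr(roc_i, fpr_grid)
    if (keep_null_rocs) null_rocs[[i]] <- roc_i
  }
  percentile <- colMeans(sweep(null_tpr, 2, target_tpr, `<`))
  structure(list(fpr_grid = fpr_grid, target_tpr = target_tpr,
                 null_tpr_median = apply(null_tpr, 2, stats::median),
                 percentile = percentile, n_null = n_null,
                 outperforms_q = min(percentile), target_roc = target_roc,
                 null_tpr = null_tpr, null_rocs = null_rocs,
                 background = background),
            class = "null_ranking")
}

#' @export
print.null_ranking <- function(x, ...) {
  df <- data.frame(fpr = x$fpr_grid, target_tpr = round(x$target_tpr, 3),
                   null_median_tpr = round(x$null_tpr_median, 3),
                   percentile = round(x$percentile, 4))
  print(df, row.names = FALSE)
  cat(sprintf("min percentile over grid: %.4f (n_null = %d)\n",
              x$outperforms_q, x$n_null))
  invisible(x)
}

#' Select the null-calibrated threshold t'
#'
#' For each candidate threshold on the target curve, computes the difference
#' between the target's TPR and the median across null curves of the TPR at
#' the target's FPR (step interpolation), and returns the threshold
#' maximizing that difference, breaking ties towards the larger (more
#' stringent) threshold.
#'
#' @param target_roc The target [build_roc()] curve.
#' @param null_rocs Non-empty list of null ROC curves built on the same
#'   sequence sets.
#' @return The threshold `t_prime` (numeric), with the per-candidate gap
#'   table as attribute `"gaps"`.
#' @export
select_threshold_tprime <- function(target_roc, null_rocs) {
  if (!length(null_rocs)) stop("empty null set")
  finite <- is.finite(target_roc$thresholds)
  cand <- target_roc$thresholds[finite]
  tpr_c <- target_roc$tpr[finite]
  fpr_c <- target_roc$fpr[finite]
  null_med <- vapply(seq_along(cand), function(j) {
    stats::median(vapply(null_rocs, roc_tpr_at_fpr, numeric(1),
                         fpr = fpr_c[j]))
  }, numeric(1))
  delta <- tpr_c - null_med
  best <- which(delta >= max(delta) - 1e-12)
  pick <- best[which.max(cand[best])]
  structure(cand[pick],
            gaps = data.frame(threshold = cand, tpr = tpr_c, fpr = fpr_c,
                              null_median_tpr = null_med, delta = delta))
}
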