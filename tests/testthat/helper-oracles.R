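# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain binomial-coefficient arithmetic for the
# hypergeometric machinery, and direct O(L^2)/exhaustive references for
# scanning and threshold selection.

BASES <- c("A", "C", "G", "T")

oracle_hyper_pmf <- function(N, m, n) {
  lo <- max(0, n - (N - m)); hi <- min(m, n)
  supp <- lo:hi
  list(supp = supp,
       pmf = choose(m, supp) * choose(N - m, n - supp) / choose(N, n))
}

oracle_hyper_tail <- function(N, m, n, k, tail) {
  o <- oracle_hyper_pmf(N, m, n)
  if (tail == "greater") sum(o$pmf[o$supp >= k]) else sum(o$pmf[o$supp <= k])
}

oracle_fisher_two_sided <- function(N, m, n, k) {
  o <- oracle_hyper_pmf(N, m, n)
  pk <- o$pmf[o$supp == k]
  sum(o$pmf[o$pmf <= pk * (1 + 1e-07)])
}

rand_seq <- function(len, probs = rep(0.25, 4)) {
  paste(sample(BASES, len, replace = TRUE, prob = probs), collapse = "")
}

rand_test_pssm <- function(width) {
  probs <- matrix(runif(4 * width, 0.05, 1), 4, width)
  probs <- sweep(probs, 2, colSums(probs), "/")
  new_pssm(probs)
}

# Direct per-base window scoring + explicit greedy collapse of overlapping
# windows (highest score first, leftmost on ties).
brute_scan <- function(pssm, seq, region = 99) {
  w <- pssm$length
  lo <- log2(pssm$probs / pssm$background)
  region <- min(region, nchar(seq))
  W <- region - w + 1
  chars <- strsplit(substr(seq, 1, region), "")[[1]]
  scores <- vapply(seq_len(W), function(s) {
    sum(vapply(seq_len(w), function(j)
      lo[match(chars[s + j - 1], BASES), j], numeric(1)))
  }, numeric(1))
  remaining <- seq_len(W)
  kept <- integer(0)
  while (length(remaining)) {
    best <- remaining[order(-scores[remaining], remaining)][1]
    kept <- c(kept, best)
    remaining <- remaining[abs(remaining - best) >= w]
  }
  kept <- sort(kept)
  data.frame(position = kept - 1L, score = scores[kept])
}

brute_tstar <- function(max_pos, max_neg) {
  cand <- sort(unique(c(max_pos, max_neg)))
  ps <- vapply(cand, function(t) {
    a <- sum(max_pos >= t); b <- sum(max_neg >= t)
    oracle_hyper_tail(length(max_pos) + length(max_neg), length(max_pos),
                      a + b, a, "greater")
  }, numeric(1))
  best <- max(which(ps <= min(ps) * (1 + 1e-12)))
  list(t_star = cand[best], p = ps[best])
}

brute_roc <- function(max_pos, max_neg) {
  thr <- c(Inf, sort(unique(c(max_pos, max_neg)), decreasing = TRUE))
  data.frame(threshold = thr,
             tpr = vapply(thr, function(t) mean(max_pos >= t), numeric(1)),
             fpr = vapply(thr, function(t) mean(max_neg >= t), numeric(1)))
}

brute_tpr_at_fpr <- function(roc_df, g) {
  ok <- roc_df$fpr <= g
  if (!any(ok)) 0 else max(roc_df$tpr[ok])
}

brute_tprime <- function(target_df, null_dfs) {
  finite <- is.finite(target_df$threshold)
  cand <- target_df$threshold[finite]
  delta <- vapply(which(finite), function(j) {
    med <- median(vapply(null_dfs, brute_tpr_at_fpr, numeric(1),
                         g = target_df$fpr[j]))
    target_df$tpr[j] - med
  }, numeric(1))
  best <- which(delta >= max(delta) - 1e-12)
  cand[best][which.max(cand[best])]
}

# Minimal transcript-record builder for tests that do not need sequences
# from the generator.
make_records <- function(n, cds_len = 150, utr5 = NULL, has_5ui = NULL,
                         leader = "SSCR", seed = 1) {
  withr::with_seed(seed, {
    data.frame(
      transcript_id = sprintf("T%04d", seq_len(n)),
      cds = vapply(seq_len(n), function(i) rand_seq(cds_len), character(1)),
      utr5_length = as.integer(utr5 %||% sample(20:400, n, replace = TRUE)),
      utr5_intron_count = as.integer(has_5ui %||% rep(0, n)),
      has_5ui = as.logical(has_5ui %||% rep(FALSE, n)),
      leader_class = rep(leader, length.out = n),
      stringsAsFactors = FALSE)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
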