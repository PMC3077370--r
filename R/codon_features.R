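# Leader-window codon composition: adenine content, paired amino-acid
# preferences (L:I, R:K) and the adenine-/thymine-lacking synonymous codon
# classes, computed on the first 69 nt of the CDS versus the rest.

# Amino acids possessing both adenine-lacking and adenine-containing codons,
# and the analogous set for thymine.
.ADENINE_AA <- c("L", "V", "A", "P", "S", "G", "R")
.THYMINE_AA <- c("A", "T", "P", "H", "N", "D", "R", "S", "G")

.codon_env <- new.env(parent = emptyenv())

.codon_tables <- function() {
  if (is.null(.codon_env$aa)) {
    gc <- Biostrings::GENETIC_CODE
    .codon_env$aa <- gc
    .codon_env$has_a <- grepl("A", names(gc), fixed = TRUE)
    .codon_env$has_t <- grepl("T", names(gc), fixed = TRUE)
    names(.codon_env$has_a) <- names(gc)
    names(.codon_env$has_t) <- names(gc)
  }
  .codon_env
}

#' Split a CDS into the 69-nt leader window and the remainder
#'
#' @param cds Coding sequence (length a multiple of 3, at least 150 nt).
#' @return List with `first69` and `rest`; their concatenation is the CDS.
#' @export
partition_cds <- function(cds) {
  n <- nchar(cds)
  if (n %% 3 != 0 || n < 150)
    stop("CDS must be a multiple of 3 and at least 150 nt")
  list(first69 = substr(cds, 1, 69), rest = substr(cds, 70, n))
}

#' Codon composition features of an in-frame sequence
#'
#' Counts adenines, amino acids (standard genetic code; stops excluded from
#' amino-acid tallies) and the adenine-lacking/-containing codon classes over
#' the seven amino acids with both types, plus the analogous thymine classes
#' over the nine. A codon is "adenine-lacking" iff none of its three bases is
#' `A`.
#'
#' @param seq In-frame nucleotide sequence over A/C/G/T, length a multiple
#'   of 3.
#' @param window Label stored with the result (`"first69"` or `"rest"`).
#' @return Object of class `codon_features`.
#' @export
codon_feature_vector <- function(seq, window = c("first69", "rest")) {
  window <- match.arg(window)
  n <- nchar(seq)
  if (n %% 3 != 0) stop("sequence length must be a multiple of 3")
  if (grepl("[^ACGT]", seq)) stop("ambiguous base in sequence")
  tb <- .codon_tables()
  codons <- substring(seq, seq(1, n, 3), seq(3, n, 3))
  aa <- unname(tb$aa[codons])
  has_a <- unname(tb$has_a[codons])
  has_t <- unname(tb$has_t[codons])
  sense <- aa != "*"
  aa_counts <- table(factor(aa[sense], levels = sort(unique(tb$aa[tb$aa != "*"]))))
  in_a <- sense & aa %in% .ADENINE_AA
  in_t <- sense & aa %in% .THYMINE_AA
  adenine_count <- sum(strsplit(seq, "")[[1]] == "A")
  structure(list(
    window = window,
    window_length = n,
    adenine_count = adenine_count,
    adenine_percent = 100 * adenine_count / n,
    aa_counts = stats::setNames(as.integer(aa_counts), names(aa_counts)),
    adenineless_codons = sum(in_a & !has_a),
    adenineful_codons = sum(in_a & has_a),
    thymineless_codons = sum(in_t & !has_t),
    thymineful_codons = sum(in_t & has_t)),
    class = "codon_features")
}

#' Per-transcript feature table over both windows
#'
#' @param records Transcript-record data.frame (filtered CDS).
#' @return Data.frame, one row per transcript x window, with the feature
#'   columns plus `transcript_id` and `window`.
#' @export
codon_feature_table <- function(records) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    parts <- partition_cds(records$cds[i])
    lapply(c("first69", "rest"), function(w) {
      fv <- codon_feature_vector(parts[[if (w == "first69") "first69" else "rest"]],
                                 window = w)
      data.frame(transcript_id = records$transcript_id[i], window = w,
                 adenine_count = fv$adenine_count,
                 adenine_percent = fv$adenine_percent,
                 L = fv$aa_counts[["L"]], I = fv$aa_counts[["I"]],
                 R = fv$aa_counts[["R"]], K = fv$aa_counts[["K"]],
                 adenineless_codons = fv$adenineless_codons,
                 adenineful_codons = fv$adenineful_codons,
                 thymineless_codons = fv$thymineless_codons,
                 thymineful_codons = fv$thymineful_codons,
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, unlist(rows, recursive = FALSE))
}

.feature_counts <- function(group, fields) {
  get1 <- function(fv, f) {
    if (f %in% names(fv)) fv[[f]] else fv$aa_counts[[f]]
  }
  vapply(fields, function(f)
    sum(vapply(group, get1, numeric(1), f = f)), numeric(1))
}

#' Compare a codon feature between two groups
#'
#' For `adenine_percent`: Wilcoxon rank-sum on per-sequence values, group
#' medians with bootstrap SEs, and the relative median difference
#' `(median2 - median1)/median2` (how much lower group 1 is) with a bootstrap
#' SE. For the paired amino-acid and codon-class ratios: Fisher's exact test
#' on the pooled counts (the ratio-of-sums presentation that yields odds
#' ratios with Woolf CIs), alongside the per-gene mean ratio with genes
#' lacking the denominator dropped and counted.
#'
#' @param group1,group2 Lists of [codon_feature_vector()] results; by
#'   convention group 1 is the 5UI- (depleted) set, group 2 the 5UI+ set.
#' @param feature One of `"adenine_percent"`, `"leu_ile"`, `"arg_lys"`,
#'   `"adenine_codon_ratio"`, `"thymine_codon_ratio"`.
#' @param B Bootstrap resamples for median SEs.
#' @param seed Seed for the bootstrap.
#' @return A list with the test ([test_result()]) and group summaries.
#' @export
compare_groups <- function(group1, group2,
                           feature = c("adenine_percent", "leu_ile",
                                       "arg_lys", "adenine_codon_ratio",
                                       "thymine_codon_ratio"),
                           B = 1000L, seed = 1L) {
  feature <- match.arg(feature)
  if (!length(group1) || !length(group2)) stop("both groups must be non-empty")
  if (feature == "adenine_percent") {
    x1 <- vapply(group1, `[[`, numeric(1), "adenine_percent")
    x2 <- vapply(group2, `[[`, numeric(1), "adenine_percent")
    med1 <- stats::median(x1); med2 <- stats::median(x2)
    rel <- (med2 - med1) / med2
    rel_boot <- withr::with_seed(derive_seed(seed, 7L), {
      vapply(seq_len(B), function(i) {
        m1 <- stats::median(sample(x1, replace = TRUE))
        m2 <- stats::median(sample(x2, replace = TRUE))
        (m2 - m1) / m2
      }, numeric(1))
    })
    rel_se <- stats::sd(rel_boot)
    return(list(
      feature = feature,
      test = wilcoxon_rank_sum(x1, x2, mode = "normal_approx"),
      median_group1 = med1, median_group2 = med2,
      median_se_group1 = bootstrap_median_se(x1, B = B, seed = derive_seed(seed, 1L)),
      median_se_group2 = bootstrap_median_se(x2, B = B, seed = derive_seed(seed, 2L)),
      relative_median_difference = rel,
      relative_median_difference_se = rel_se,
      relative_median_difference_ci =
        c(rel - 1.959964 * rel_se, rel + 1.959964 * rel_se)))
  }
  fields <- switch(feature,
    leu_ile = c("L", "I"),
    arg_lys = c("R", "K"),
    adenine_codon_ratio = c("adenineless_codons", "adenineful_codons"),
    thymine_codon_ratio = c("thymineless_codons", "thymineful_codons"))
  c1 <- unname(.feature_counts(group1, fields))
  c2 <- unname(.feature_counts(group2, fields))
  tbl <- contingency_2x2(c1[1], c1[2], c2[1], c2[2])
  get_pair <- function(fv) {
    v <- vapply(fields, function(f)
      if (f %in% names(fv)) fv[[f]] else fv$aa_counts[[f]], numeric(1))
    v
  }
  per_gene_ratio <- function(group) {
    pairs <- vapply(group, get_pair, numeric(2))
    ok <- pairs[2, ] > 0
    list(mean_ratio = if (any(ok)) mean(pairs[1, ok] / pairs[2, ok]) else NA_real_,
         n_dropped = sum(!ok))
  }
  pg1 <- per_gene_ratio(group1); pg2 <- per_gene_ratio(group2)
  list(feature = feature,
       test = fisher_exact_2x2(tbl, tail = "two_sided"),
       pooled_counts_group1 = c1, pooled_counts_group2 = c2,
       pooled_ratio_group1 = unname(c1[1] / c1[2]),
       pooled_ratio_group2 = unname(c2[1] / c2[2]),
       per_gene_mean_ratio_group1 = pg1$mean_ratio,
       per_gene_mean_ratio_group2 = pg2$mean_ratio,
       per_gene_dropped = c(group1 = pg1$n_dropped, group2 = pg2$n_dropped))
}
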