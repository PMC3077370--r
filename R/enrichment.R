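# Category enrichment of 5UI status: per-term Fisher tests ranked by LOD
# (log10 odds ratio), a min-p label-resampling multiple-testing adjustment
# that preserves the dependency structure among terms, and a stratified
# (Cochran-Mantel-Haenszel) control for 5'UTR length.

#' Read flat category annotations
#'
#' Two-column TSV (`term_id`, `transcript_id`), GAF-like; `#` comment lines
#' ignored. Terms are flat sets -- no ontology propagation.
#'
#' @param path File path.
#' @return Named list mapping term id to character vector of member ids.
#' @export
read_term_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t")
  bad <- lengths(parts) < 2L
  if (any(bad)) stop("malformed annotation line: ", lines[which(bad)[1]])
  term <- vapply(parts, `[[`, character(1), 1L)
  id <- vapply(parts, `[[`, character(1), 2L)
  lapply(split(id, term), unique)
}

.term_lod <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells == 0)) cells <- cells + 0.5
  log10((cells[1] * cells[4]) / (cells[2] * cells[3]))
}

#' Per-term enrichment of 5UI status
#'
#' For every term, a two-sided Fisher's exact test of the 2x2 (in-term x
#' 5UI+) table, the LOD (log10 odds ratio, Haldane-corrected when a cell is
#' zero), and the raw counts. Positive LOD means the term is enriched for
#' 5UI-containing genes, negative means depleted.
#'
#' @param annotations Named list of term member-id vectors.
#' @param labels Named logical vector over all transcripts (`TRUE` = has a
#'   5'UTR intron). Every member id must be labeled.
#' @param view `"enrichment"` sorts by descending LOD, `"depletion"` by
#'   ascending LOD.
#' @return Data.frame: `term_id`, `n_term`, `k_5ui`, `N`, `m_5ui`, `lod`,
#'   `p_raw`.
#' @export
term_enrichment <- function(annotations, labels,
                            view = c("enrichment", "depletion")) {
  view <- match.arg(view)
  if (is.null(names(labels))) stop("labels must be named by transcript id")
  ids <- names(labels)
  N <- length(labels); m <- sum(labels)
  rows <- lapply(names(annotations), function(term) {
    members <- annotations[[term]]
    unknown <- setdiff(members, ids)
    if (length(unknown))
      stop("unlabeled transcript in term ", term, ": ", unknown[1])
    s <- length(members)
    k <- sum(labels[members])
    a <- k; b <- s - k; c <- m - k; d <- (N - m) - (s - k)
    ft <- fisher_exact_2x2(contingency_2x2(a, b, c, d), "two_sided")
    data.frame(term_id = term, n_term = s, k_5ui = k, N = N, m_5ui = m,
               lod = .term_lod(a, b, c, d), p_raw = ft$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(if (view == "enrichment") -out$lod else out$lod,
                   out$p_raw), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Min-p resampling adjustment of term p-values
#'
#' Westfall-Young style: permutes the 5UI labels over transcripts (keeping
#' the number of labeled transcripts fixed, hence preserving the dependency
#' structure among overlapping terms), records the minimum raw p across all
#' terms per permutation, and sets `p_adj(term) = (1 + #\{permutations with
#' min p <= p_raw\}) / (1 + n_resamples)` with monotone step-down
#' enforcement in `p_raw`.
#'
#' @param rows Output of [term_enrichment()].
#' @param annotations The same term list used to build `rows`.
#' @param labels The observed label vector.
#' @param n_resamples Number of label permutations (default 10000).
#' @param seed Integer seed.
#' @return `rows` with a `p_adj` column appended.
#' @export
resampling_adjust <- function(rows, annotations, labels,
                              n_resamples = 10000L, seed = 1L) {
  ids <- names(labels)
  N <- length(labels); m <- sum(labels)
  member_idx <- lapply(rows$term_id, function(t)
    match(annotations[[t]], ids))
  sizes <- lengths(member_idx)
  # two-sided Fisher p as a function of the in-term 5UI count, per term
  p_profiles <- lapply(sizes, function(s) {
    prof <- .fisher_two_sided_profile(N, m, s)
    lo <- as.integer(names(prof)[1])
    list(p = unname(prof), lo = lo)
  })
  lab_num <- as.numeric(labels)
  min_p <- withr::with_seed(seed, {
    vapply(seq_len(n_resamples), function(b) {
      perm <- sample(lab_num)
      min(vapply(seq_along(member_idx), function(t) {
        k <- sum(perm[member_idx[[t]]])
        pp <- p_profiles[[t]]
        pp$p[k - pp$lo + 1L]
      }, numeric(1)))
    }, numeric(1))
  })
  p_adj <- vapply(rows$p_raw, function(p)
    (1 + sum(min_p <= p)) / (1 + n_resamples), numeric(1))
  # monotone in p_raw
  ord <- order(rows$p_raw)
  p_adj[ord] <- cummax(p_adj[ord])
  rows$p_adj <- pmin(pmax(p_adj, rows$p_raw), 1)
  rows
}

#' Length-matched association of leader class with 5UI status
#'
#' Stratifies transcripts into 5'UTR-length quantile bins and tests the
#' association between leader-class membership and 5UI presence across
#' strata with the Cochran-Mantel-Haenszel common odds-ratio test -- a
#' control for the confounding of 5UI presence with 5'UTR length. Strata
#' with a zero margin are dropped with a warning.
#'
#' @param records Transcript-record data.frame with `utr5_length`,
#'   `has_5ui`, `leader_class`.
#' @param n_strata Number of length-quantile strata (default 10).
#' @param leader Leader class defining membership (default `"SSCR"`).
#' @return An [test_result()] with the common odds ratio as effect;
#'   per-stratum tables in attribute `"strata"`.
#' @export
length_matched_association <- function(records, n_strata = 10L,
                                       leader = "SSCR") {
  x <- factor(records$leader_class == leader, levels = c(TRUE, FALSE))
  y <- factor(records$has_5ui, levels = c(TRUE, FALSE))
  breaks <- unique(stats::quantile(records$utr5_length,
                                   probs = seq(0, 1, length.out = n_strata + 1)))
  strata <- if (length(breaks) > 2) {
    cut(records$utr5_length, breaks = breaks, include.lowest = TRUE)
  } else factor(rep("all", nrow(records)))
  tab <- table(x, y, strata)
  ok <- apply(tab, 3, function(t2)
    all(rowSums(t2) > 0) && all(colSums(t2) > 0))
  if (!all(ok))
    warning(sum(!ok), " stratum/strata with a zero margin dropped")
  tab <- tab[, , ok, drop = FALSE]
  if (dim(tab)[3] == 0) stop("no usable stratum")
  res <- if (dim(tab)[3] == 1L) {
    # one stratum: the CMH statistic reduces to the plain 2x2 association
    t2 <- tab[, , 1]
    ft <- fisher_exact_2x2(contingency_2x2(t2[1, 1], t2[1, 2],
                                           t2[2, 1], t2[2, 2]))
    ft$method <- "Cochran-Mantel-Haenszel (single stratum: plain 2x2 Fisher)"
    ft
  } else {
    mh <- stats::mantelhaen.test(tab, exact = FALSE, correct = TRUE)
    test_result(statistic = unname(mh$statistic), p_value = mh$p.value,
                effect = unname(mh$estimate %||% NA_real_),
                ci_lower = if (!is.null(mh$conf.int)) mh$conf.int[1] else NA_real_,
                ci_upper = if (!is.null(mh$conf.int)) mh$conf.int[2] else NA_real_,
                method = "Cochran-Mantel-Haenszel (5'UTR-length strata)")
  }
  attr(res, "strata") <- tab
  res
}

#' Write a term-enrichment report as TSV
#'
#' Columns mirror the LOD-sorted category report: term, counts, LOD, raw and
#' adjusted p.
#'
#' @param rows Output of [resampling_adjust()] (or [term_enrichment()]).
#' @param path Output file.
#' @export
write_enrichment_report <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
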