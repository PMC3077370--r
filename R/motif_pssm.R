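# PSSM construction, window scoring over the first 99 nt of each CDS,
# overlap disambiguation, the enrichment-optimal threshold t*, occurrence
# analyses (presence, multiplicity, frame, position), and an exhaustive
# degenerate k-mer discriminative scan (a labeled stand-in for external
# discriminative motif finders).

.BASES <- c("A", "C", "G", "T")

#' Construct a PSSM object
#'
#' @param probs 4 x width column-stochastic matrix, rows A/C/G/T.
#' @param background Length-4 background frequency vector summing to 1.
#' @param name Motif name.
#' @return Object of class `pssm`.
#' @export
new_pssm <- function(probs, background = rep(0.25, 4), name = "pssm") {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) stop("probs must have 4 rows (A, C, G, T)")
  if (ncol(probs) < 4L) stop("motif width must be at least 4")
  if (any(abs(colSums(probs) - 1) > 1e-09))
    stop("PSSM columns must sum to 1")
  if (abs(sum(background) - 1) > 1e-09 || any(background <= 0))
    stop("background must be positive and sum to 1")
  rownames(probs) <- .BASES
  structure(list(probs = probs, background = stats::setNames(background, .BASES),
                 length = ncol(probs), name = name),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM '%s' (width %d)\n", x$name, x$length))
  print(round(x$probs, 3))
  invisible(x)
}

#' Build a PSSM from aligned sites
#'
#' Column probabilities are `(count + pseudocount) / (n_sites + 4 *
#' pseudocount)`.
#'
#' @param sites Two or more equal-length A/C/G/T strings.
#' @param pseudocount Per-base pseudocount (default 0.5).
#' @param background Background frequencies.
#' @param name Motif name.
#' @return A [new_pssm()] object.
#' @export
pssm_from_sites <- function(sites, pseudocount = 0.5,
                            background = rep(0.25, 4), name = "sites") {
  if (length(sites) < 2L) stop("need at least 2 sites")
  w <- unique(nchar(sites))
  if (length(w) != 1L) stop("sites must have identical lengths")
  mat <- vapply(seq_len(w), function(j) {
    col <- substr(sites, j, j)
    counts <- vapply(.BASES, function(b) sum(col == b), numeric(1))
    (counts + pseudocount) / (length(sites) + 4 * pseudocount)
  }, numeric(4))
  new_pssm(mat, background = background, name = name)
}

# IUPAC degenerate consensus -> all concrete instantiations
.expand_consensus <- function(consensus) {
  map <- Biostrings::IUPAC_CODE_MAP
  letters_ok <- strsplit(toupper(consensus), "")[[1]]
  if (!all(letters_ok %in% names(map))) stop("unknown IUPAC letter in consensus")
  sets <- strsplit(map[letters_ok], "")
  n_inst <- prod(lengths(sets))
  if (n_inst > 4096) stop("consensus too degenerate to expand")
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1, paste, collapse = "")
}

#' PSSM from a degenerate consensus
#'
#' Expands the IUPAC consensus (e.g. `CGSSGC`, S = C/G) into all concrete
#' instantiations and builds a pseudocounted PSSM from them.
#'
#' @param consensus IUPAC string.
#' @inheritParams pssm_from_sites
#' @return A [new_pssm()] object.
#' @export
consensus_pssm <- function(consensus, pseudocount = 0.5,
                           background = rep(0.25, 4), name = consensus) {
  pssm_from_sites(.expand_consensus(consensus), pseudocount = pseudocount,
                  background = background, name = name)
}

# Encode sequences (first `region` nt) as an n x region integer matrix.
.encode_region <- function(seqs, region) {
  if (any(nchar(seqs) < region))
    stop("sequence shorter than scan region (", region, " nt)")
  m <- matrix(0L, nrow = length(seqs), ncol = region)
  chunk <- substr(seqs, 1, region)
  raw <- matrix(match(unlist(strsplit(chunk, ""), use.names = FALSE), .BASES),
                nrow = region)
  if (anyNA(raw)) stop("non-ACGT base in scan region")
  t(raw)
}

# Window log-odds scores (bits) for one PSSM over an encoded region matrix.
# Returns n x (region - width + 1).
.window_scores <- function(pssm, codes) {
  w <- pssm$length
  region <- ncol(codes)
  if (region < w) stop("scan region shorter than motif width")
  lo <- log2(pmax(pssm$probs, 1e-300) / pssm$background)
  W <- region - w + 1L
  n <- nrow(codes)
  S <- matrix(0, n, W)
  for (j in seq_len(w)) {
    S <- S + matrix(lo[cbind(as.vector(codes[, j:(j + W - 1L), drop = FALSE]),
                             j)], n, W)
  }
  S
}

#' Maximum PSSM score per sequence
#'
#' The maximum log-odds window score within the first `region` nt; the basis
#' of motif-containing classification and the ROC machinery.
#'
#' @param pssm A [new_pssm()] object.
#' @param seqs Character vector of sequences (each at least `region` nt).
#' @param region Scan region length in nt.
#' @return Numeric vector of per-sequence maxima.
#' @export
pssm_max_scores <- function(pssm, seqs, region = 99L) {
  codes <- if (is.matrix(seqs)) seqs else .encode_region(seqs, region)
  S <- .window_scores(pssm, codes)
  apply(S, 1, max)
}

# Greedy score-descending non-maximum suppression with leftmost tie-break.
.nms_retain <- function(scores, width) {
  W <- length(scores)
  ord <- order(-scores, seq_len(W))
  keep <- logical(W)
  blocked <- logical(W)
  for (i in ord) {
    if (blocked[i]) next
    keep[i] <- TRUE
    blocked[max(1L, i - width + 1L):min(W, i + width - 1L)] <- TRUE
  }
  which(keep)
}

#' Scan one sequence with a PSSM
#'
#' Scores every window of the motif width within the first `region` nt as the
#' sum of per-base log2 odds against the background, then disambiguates
#' overlaps: among mutually overlapping windows only the highest-scoring one
#' is retained (ties broken leftmost), applied greedily in descending score
#' order so retained hits never overlap. No threshold is applied here; hits
#' are filtered downstream.
#'
#' @param pssm A [new_pssm()] object.
#' @param cds Sequence to scan (at least `region` nt).
#' @param region Scan region (default 99 nt).
#' @param transcript_id Optional id recorded with the hits.
#' @return Data.frame of hits: `transcript_id`, `position` (0-based offset),
#'   `frame` (`position %% 3`), `score` (bits).
#' @export
scan_sequence <- function(pssm, cds, region = 99L, transcript_id = NA_character_) {
  if (region < pssm$length) stop("region shorter than motif width")
  codes <- .encode_region(cds, min(region, nchar(cds)))
  s <- .window_scores(pssm, codes)[1, ]
  kept <- .nms_retain(s, pssm$length)
  data.frame(transcript_id = transcript_id, position = kept - 1L,
             frame = (kept - 1L) %% 3L, score = s[kept],
             stringsAsFactors = FALSE)
}

#' Scan a set of transcripts
#'
#' @param pssm A [new_pssm()] object.
#' @param records Transcript-record data.frame (`transcript_id`, `cds`).
#' @param region Scan region in nt.
#' @return Row-bound hit data.frame (see [scan_sequence()]).
#' @export
scan_transcripts <- function(pssm, records, region = 99L) {
  codes <- .encode_region(records$cds, region)
  S <- .window_scores(pssm, codes)
  width <- pssm$length
  hits <- lapply(seq_len(nrow(S)), function(i) {
    kept <- .nms_retain(S[i, ], width)
    data.frame(transcript_id = records$transcript_id[i], position = kept - 1L,
               frame = (kept - 1L) %% 3L, score = S[i, kept],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, hits)
}

#' Select the enrichment-optimal score threshold t*
#'
#' Sweeps the distinct observed per-sequence maxima as candidate thresholds;
#' at each, sequences with maximum score >= t are classified motif-containing
#' and the greater-tail hypergeometric probability of the resulting 2x2 table
#' (positive class x motif-containing) is computed. Returns the threshold
#' minimizing that p, breaking ties towards the larger (more stringent)
#' threshold.
#'
#' @param max_scores_pos,max_scores_neg Per-sequence maximum scores for the
#'   positive (5UI-) and negative (5UI+) sets.
#' @return List with `t_star`, `fisher_p` (the greater-tail p at `t_star`)
#'   and `table_at_t` (the [contingency_2x2()]).
#' @export
select_threshold_tstar <- function(max_scores_pos, max_scores_neg) {
  if (!length(max_scores_pos) || !length(max_scores_neg))
    stop("both score lists must be non-empty")
  cand <- sort(unique(c(max_scores_pos, max_scores_neg)))
  n_pos <- length(max_scores_pos); n_neg <- length(max_scores_neg)
  sp <- sort(max_scores_pos); sn <- sort(max_scores_neg)
  # counts >= t via findInterval on sorted scores
  a <- n_pos - findInterval(cand, sp, left.open = TRUE)
  b <- n_neg - findInterval(cand, sn, left.open = TRUE)
  p <- vapply(seq_along(cand), function(i)
    hypergeom_tail(contingency_2x2(a[i], b[i], n_pos - a[i], n_neg - b[i]),
                   "greater"), numeric(1))
  best <- max(which(p <= min(p) * (1 + 1e-12)))
  list(t_star = cand[best], fisher_p = p[best],
       table_at_t = contingency_2x2(a[best], b[best],
                                    n_pos - a[best], n_neg - b[best]))
}

#' Occurrence statistics of thresholded motif hits
#'
#' Splits sequences into the positive (5UI-) and negative (5UI+) groups and
#' reports, per group: the fraction of sequences with at least one and at
#' least two hits at the supplied threshold, the per-frame occurrence
#' fractions with a chi-square test against uniform 1/3, and the positions of
#' all occurrences (0-based window starts; also reported 1-based) with their
#' medians and a cross-group Wilcoxon rank-sum test.
#'
#' @param hits Hit data.frame from [scan_transcripts()].
#' @param labels Named logical vector over all scanned sequence ids: `TRUE`
#'   if the sequence has a 5'UTR intron (negative set).
#' @param threshold Score threshold (hits with `score >= threshold` count).
#' @return List of class `occurrence_report`.
#' @export
occurrence_stats <- function(hits, labels, threshold) {
  if (is.null(names(labels))) stop("labels must be named by transcript id")
  th <- hits[hits$score >= threshold, , drop = FALSE]
  ids <- names(labels)
  counts <- table(factor(th$transcript_id, levels = ids))
  grp <- function(neg) {
    sel <- labels == neg
    n <- sum(sel)
    cn <- counts[sel]
    hsel <- th$transcript_id %in% ids[sel]
    frames <- tabulate(th$frame[hsel] + 1L, nbins = 3L)
    positions <- th$position[hsel]
    list(n_sequences = n,
         frac_ge1 = if (n) sum(cn >= 1) / n else NA_real_,
         frac_ge2 = if (n) sum(cn >= 2) / n else NA_real_,
         n_occurrences = sum(frames),
         frame_counts = frames,
         frame_fractions = if (sum(frames)) frames / sum(frames) else rep(NA_real_, 3),
         frame_chisq_p = if (sum(frames) > 0)
           suppressWarnings(stats::chisq.test(frames, p = rep(1/3, 3))$p.value)
           else NA_real_,
         positions = positions,
         median_position = if (length(positions)) stats::median(positions) else NA_real_,
         median_position_1based = if (length(positions))
           stats::median(positions) + 1 else NA_real_)
  }
  pos_grp <- grp(FALSE)  # 5UI- (positive set)
  neg_grp <- grp(TRUE)   # 5UI+
  position_test <- if (length(pos_grp$positions) && length(neg_grp$positions)) {
    wilcoxon_rank_sum(pos_grp$positions, neg_grp$positions,
                      mode = "normal_approx")
  } else NULL
  structure(list(threshold = threshold, group_5ui_minus = pos_grp,
                 group_5ui_plus = neg_grp, position_test = position_test,
                 position_convention = "0-based window start (median also 1-based)"),
            class = "occurrence_report")
}

#' @export
print.occurrence_report <- function(x, ...) {
  cat(sprintf("Occurrence report at threshold %.3f\n", x$threshold))
  for (g in c("group_5ui_minus", "group_5ui_plus")) {
    gg <- x[[g]]
    cat(sprintf("  %s: n=%d, >=1 hit %.1f%%, >=2 hits %.1f%%, median pos (1-based) %s\n",
                sub("group_", "", g), gg$n_sequences, 100 * gg$frac_ge1,
                100 * gg$frac_ge2, format(gg$median_position_1based)))
  }
  if (!is.null(x$position_test))
    cat(sprintf("  positional Wilcoxon p = %.3g\n", x$position_test$p_value))
  invisible(x)
}

# Degenerate alphabet for the exhaustive k-mer scan.
.KMER_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   S = c("C", "G"), W = c("A", "T"))

#' Exhaustive discriminative degenerate k-mer scan
#'
#' A simple, explicitly labeled stand-in for external discriminative motif
#' finders: enumerates every degenerate k-mer over the given alphabet, scores
#' presence/absence within the first `region` nt of each sequence, and ranks
#' k-mers by the greater-tail hypergeometric probability of presence in the
#' positive versus negative set, with Bonferroni adjustment over the
#' enumeration size.
#'
#' @param pos_seqs,neg_seqs Character vectors of sequences.
#' @param k Motif length (at most 8).
#' @param alphabet Letters drawn from A, C, G, T, S (C/G), W (A/T).
#' @param region Scan region in nt.
#' @param top Number of top-ranked motifs to return (all if `Inf`).
#' @return Data.frame ranked by p: `kmer`, `present_pos`, `present_neg`,
#'   `p_raw`, `p_bonferroni`.
#' @export
discriminative_kmer_scan <- function(pos_seqs, neg_seqs, k = 6L,
                                     alphabet = c("A", "C", "G", "T", "S", "W"),
                                     region = 99L, top = Inf) {
  if (k > 8L) stop("k > 8 refused (combinatorial guard)")
  if (!all(alphabet %in% names(.KMER_SETS))) stop("unsupported alphabet letter")
  n_pos <- length(pos_seqs); n_neg <- length(neg_seqs)
  if (any(nchar(c(pos_seqs, neg_seqs)) < k)) stop("sequence shorter than k")
  # presence matrix over exact k-mers: which of the 4^k words occur per seq
  presence_exact <- function(seqs) {
    n <- length(seqs)
    M <- matrix(FALSE, n, 4L^k)
    for (i in seq_len(n)) {
      s <- substr(seqs[i], 1, min(region, nchar(seqs[i])))
      L <- nchar(s)
      if (L < k) next
      code <- match(strsplit(s, "")[[1]], .BASES) - 1L
      idx <- 0L
      mult <- 4L^(k - 1L)
      # rolling code of each window
      win <- sum(code[1:k] * 4L^((k - 1L):0)) + 1L
      M[i, win] <- TRUE
      if (L > k) for (p in seq(2L, L - k + 1L)) {
        win <- (win - 1L - code[p - 1L] * mult) * 4L + code[p + k - 1L] + 1L
        M[i, win] <- TRUE
      }
    }
    M
  }
  Mp <- presence_exact(pos_seqs)
  Mn <- presence_exact(neg_seqs)
  sets <- .KMER_SETS[alphabet]
  grid <- do.call(expand.grid, c(rep(list(alphabet), k),
                                 stringsAsFactors = FALSE))
  n_enum <- nrow(grid)
  base_codes <- lapply(alphabet, function(a) match(.KMER_SETS[[a]], .BASES) - 1L)
  names(base_codes) <- alphabet
  kmers <- do.call(paste0, grid)
  p_raw <- numeric(n_enum)
  pres_pos <- integer(n_enum); pres_neg <- integer(n_enum)
  pow <- 4L^((k - 1L):0)
  for (r in seq_len(n_enum)) {
    codes_by_pos <- lapply(seq_len(k), function(j) base_codes[[grid[r, j]]])
    cols <- Reduce(function(acc, j) {
      as.vector(outer(acc, codes_by_pos[[j]] * pow[j], `+`))
    }, seq_len(k), accumulate = FALSE, init = 0L) + 1L
    pp <- if (length(cols) == 1L) sum(Mp[, cols]) else
      sum(rowSums(Mp[, cols, drop = FALSE]) > 0)
    pn <- if (length(cols) == 1L) sum(Mn[, cols]) else
      sum(rowSums(Mn[, cols, drop = FALSE]) > 0)
    pres_pos[r] <- pp; pres_neg[r] <- pn
    p_raw[r] <- hypergeom_tail(
      contingency_2x2(pp, pn, n_pos - pp, n_neg - pn), "greater")
  }
  out <- data.frame(kmer = kmers, present_pos = pres_pos,
                    present_neg = pres_neg, p_raw = p_raw,
                    p_bonferroni = pmin(p_raw * n_enum, 1),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_raw, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  if (is.finite(top)) out <- utils::head(out, top)
  out
}

#' Read a PSSM from file
#'
#' Supports a simple 4-row format (lines `A p1 p2 ...` etc.) and the MEME
#' minimal motif format (first `letter-probability matrix` block; background
#' taken from a `Background letter frequencies` line when present).
#'
#' @param path File path.
#' @param format `"auto"`, `"simple"` or `"meme"`.
#' @param name Motif name (defaults to MEME motif name or file name).
#' @return A [new_pssm()] object.
#' @export
read_pssm <- function(path, format = c("auto", "simple", "meme"), name = NULL) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto")
    format <- if (any(grepl("letter-probability matrix", lines))) "meme" else "simple"
  if (format == "simple") {
    rows <- lapply(.BASES, function(b) {
      ln <- grep(paste0("^", b, "[[:space:]]"), lines, value = TRUE)
      if (length(ln) != 1L) stop("simple PSSM needs exactly one row per base")
      as.numeric(strsplit(trimws(sub(paste0("^", b), "", ln)), "[[:space:]]+")[[1]])
    })
    probs <- do.call(rbind, rows)
    return(new_pssm(probs, name = name %||% basename(path)))
  }
  bg <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) && bg_at[1] < length(lines)) {
    tok <- strsplit(trimws(lines[bg_at[1] + 1L]), "[[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    lab <- tok[is.na(vals)]; num <- vals[!is.na(vals)]
    if (length(num) == 4L) bg <- num[match(.BASES, lab)]
  }
  motif_at <- grep("^MOTIF", lines)
  mat_at <- grep("letter-probability matrix", lines)[1]
  hdr <- lines[mat_at]
  w <- as.integer(sub(".*w=[[:space:]]*([0-9]+).*", "\\1", hdr))
  body <- lines[(mat_at + 1L):(mat_at + w)]
  probs <- vapply(body, function(ln)
    as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]]), numeric(4))
  dimnames(probs) <- NULL  # columns = positions, rows A C G T
  probs <- sweep(probs, 2, colSums(probs), "/")
  mname <- if (!is.null(name)) name else if (length(motif_at))
    sub("^MOTIF[[:space:]]+", "", lines[motif_at[1]]) else basename(path)
  new_pssm(probs, background = bg, name = mname)
}

#' Write a PSSM in the simple 4-row format
#'
#' @param pssm A [new_pssm()] object.
#' @param path Output file.
#' @export
write_pssm <- function(pssm, path) {
  lines <- vapply(seq_len(4), function(i)
    paste(.BASES[i], paste(format(pssm$probs[i, ], digits = 15),
                           collapse = " ")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write motif hits as TSV
#'
#' Positions are reported 1-based in the file (flagged in the header name).
#' @param hits Hit data.frame.
#' @param path Output file.
#' @export
write_hits <- function(hits, path) {
  out <- data.frame(transcript_id = hits$transcript_id,
                    position_1based = hits$position + 1L,
                    frame = hits$frame, score_bits = hits$score,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
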