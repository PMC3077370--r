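# Sequence/annotation ingest: FASTA parsing with a strict coding alphabet,
# refGene-like table parsing, 5'UTR / 5UI derivation in transcript
# orientation, the CDS filters, and splice-variant deduplication.

#' Parse coding sequences from FASTA
#'
#' Sequences are uppercased. Records whose sequence contains `N` or any
#' character outside `A/C/G/T/N` are rejected per record with a reason;
#' duplicated identifiers are a fatal error naming the offender.
#'
#' @param path FASTA file.
#' @return A list with `records` (data.frame: `transcript_id`, `cds`) and
#'   `rejects` (data.frame: `transcript_id`, `reason`).
#' @export
parse_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate transcript id in FASTA: ", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(ss))
  bad_alpha <- grepl("[^ACGTN]", seqs)
  has_n <- !bad_alpha & grepl("N", seqs, fixed = TRUE)
  keep <- !bad_alpha & !has_n
  rejects <- data.frame(
    transcript_id = ids[!keep],
    reason = ifelse(bad_alpha[!keep], "invalid alphabet", "contains N"),
    stringsAsFactors = FALSE)
  list(records = data.frame(transcript_id = ids[keep], cds = unname(seqs[keep]),
                            stringsAsFactors = FALSE),
       rejects = rejects)
}

#' Write coding sequences to FASTA
#'
#' @param records Data.frame with `transcript_id` and `cds`.
#' @param path Output file.
#' @export
write_cds_fasta <- function(records, path) {
  ss <- Biostrings::DNAStringSet(records$cds)
  names(ss) <- records$transcript_id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a refGene-like annotation table
#'
#' Expects tab-delimited columns `name`, `chrom`, `strand`, `txStart`,
#' `txEnd`, `cdsStart`, `cdsEnd`, `exonCount`, `exonStarts`, `exonEnds`
#' (0-based half-open genomic intervals, comma-separated coordinate lists,
#' UCSC convention). Exons must be sorted and non-overlapping.
#'
#' @param path Annotation file.
#' @return Data.frame with list-columns `exon_starts`, `exon_ends`.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("cannot read annotation table: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "chrom", "strand", "txStart", "txEnd",
            "cdsStart", "cdsEnd", "exonCount", "exonStarts", "exonEnds")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation table missing columns: ",
                         paste(miss, collapse = ", "))
  parse_list <- function(x) lapply(strsplit(x, ","), function(v) as.numeric(v[v != ""]))
  out <- data.frame(transcript_id = df$name, chrom = df$chrom,
                    strand = df$strand, tx_start = df$txStart,
                    tx_end = df$txEnd, cds_start = df$cdsStart,
                    cds_end = df$cdsEnd, stringsAsFactors = FALSE)
  out$exon_starts <- parse_list(df$exonStarts)
  out$exon_ends <- parse_list(df$exonEnds)
  for (i in seq_len(nrow(out))) {
    s <- out$exon_starts[[i]]; e <- out$exon_ends[[i]]
    if (length(s) != length(e) || any(e <= s) ||
        (length(s) > 1 && any(diff(s) <= 0 | utils::head(e, -1) > s[-1])))
      stop("malformed exon structure for ", out$transcript_id[i])
  }
  out
}

#' Derive 5'UTR length and 5UI count from one annotation row
#'
#' Works in transcript orientation for both strands. The 5'UTR length is the
#' total exonic length strictly 5' of the CDS start; the 5UI count is the
#' number of introns lying wholly 5' of the CDS start (an intron at the exact
#' UTR/CDS junction still counts: it is entirely upstream of the CDS). Also
#' reports the total genomic length of the remaining (non-5'UTR) introns.
#'
#' @param annotation A single-row slice of [read_annotation_table()] output,
#'   or a list with `strand`, `exon_starts`, `exon_ends`, `cds_start`,
#'   `cds_end`.
#' @return List with `utr5_length`, `utr5_intron_count`,
#'   `non_utr5_intron_total`.
#' @export
derive_utr5 <- function(annotation) {
  ann <- as.list(annotation)
  starts <- ann$exon_starts; ends <- ann$exon_ends
  if (is.list(starts)) starts <- starts[[1]]
  if (is.list(ends)) ends <- ends[[1]]
  strand <- as.character(ann$strand)
  lens <- ends - starts
  # genomic coordinate of the 5'-most CDS base
  g5 <- if (strand == "+") ann$cds_start else ann$cds_end - 1
  ex <- which(starts <= g5 & g5 < ends)
  if (length(ex) != 1L) stop("inconsistent annotation: cds start not in exon union")
  if (strand == "+") {
    order_idx <- seq_along(starts)
    offset_in <- g5 - starts[ex]
  } else {
    order_idx <- rev(seq_along(starts))
    offset_in <- ends[ex] - 1 - g5
  }
  tx_lens <- lens[order_idx]
  pos_in_order <- match(ex, order_idx)
  utr5_length <- sum(tx_lens[seq_len(pos_in_order - 1)]) + offset_in
  n_introns <- length(starts) - 1L
  utr5_intron_count <- 0L
  non_utr5_total <- 0
  if (n_introns > 0) {
    # transcript-coordinate position of each intron, in transcript order
    intron_tx_pos <- cumsum(tx_lens)[seq_len(n_introns)]
    # genomic length of each intron, in transcript order
    gaps <- starts[-1] - ends[-length(ends)]
    gaps_tx <- if (strand == "+") gaps else rev(gaps)
    is_5ui <- intron_tx_pos <= utr5_length
    utr5_intron_count <- sum(is_5ui)
    non_utr5_total <- sum(gaps_tx[!is_5ui])
  }
  list(utr5_length = as.integer(utr5_length),
       utr5_intron_count = as.integer(utr5_intron_count),
       non_utr5_intron_total = as.numeric(non_utr5_total))
}

#' Apply the CDS length filters
#'
#' Removes coding sequences whose length is not a multiple of three, then
#' those shorter than 150 nt. A sequence failing both is counted once, under
#' the first rule.
#'
#' @param records Data.frame with `transcript_id`, `cds`.
#' @return List with filtered `records` and a `report` of per-rule removals.
#' @export
apply_cds_filters <- function(records) {
  len <- nchar(records$cds)
  not3 <- len %% 3 != 0
  short <- !not3 & len < 150
  list(records = records[!(not3 | short), , drop = FALSE],
       report = c(not_multiple_of_3 = sum(not3), too_short = sum(short)))
}

#' Collapse splice variants to one representative
#'
#' Groups records by a key -- the first 69 CDS nucleotides
#' (`identical_leader69`) or the 5'UTR splicing pattern taken from the
#' annotation (`identical_utr_splicing`: chromosome, strand and the genomic
#' coordinates of all 5'UTR introns) -- and keeps one seeded-uniform random
#' representative per group.
#'
#' @param records Data.frame with `transcript_id`, `cds`.
#' @param mode Grouping key (see above).
#' @param seed Integer seed; selection is deterministic given the seed.
#' @param annotations Annotation table (required for `identical_utr_splicing`).
#' @return The representative subset of `records` (original order).
#' @export
dedup_splice_variants <- function(records,
                                  mode = c("identical_leader69",
                                           "identical_utr_splicing"),
                                  seed = 1L, annotations = NULL) {
  mode <- match.arg(mode)
  key <- if (mode == "identical_leader69") {
    substr(records$cds, 1, 69)
  } else {
    if (is.null(annotations))
      stop("identical_utr_splicing requires an annotation table")
    idx <- match(records$transcript_id, annotations$transcript_id)
    if (anyNA(idx)) stop("no annotation for transcript: ",
                         records$transcript_id[which(is.na(idx))[1]])
    vapply(idx, function(i) {
      ann <- annotations[i, ]
      d <- derive_utr5(ann)
      starts <- ann$exon_starts[[1]]; ends <- ann$exon_ends[[1]]
      n_introns <- length(starts) - 1L
      pat <- ""
      if (n_introns > 0 && d$utr5_intron_count > 0) {
        lens <- ends - starts
        ord <- if (ann$strand == "+") seq_along(starts) else rev(seq_along(starts))
        intron_pos <- cumsum(lens[ord])[seq_len(n_introns)]
        which_5ui <- which(intron_pos <= d$utr5_length)
        donors <- (ends[-length(ends)])
        accept <- (starts[-1])
        pairs <- if (ann$strand == "+") {
          paste(donors, accept, sep = "-")
        } else {
          rev(paste(donors, accept, sep = "-"))
        }
        pat <- paste(pairs[which_5ui], collapse = ";")
      }
      paste(ann$chrom, ann$strand, pat, sep = "|")
    }, character(1))
  }
  groups <- split(seq_len(nrow(records)), key)
  reps <- withr::with_seed(seed, {
    vapply(groups, function(ix) if (length(ix) == 1L) ix else
      ix[sample.int(length(ix), 1L)], integer(1))
  })
  records[sort(unname(reps)), , drop = FALSE]
}

#' Read a plain-text id list
#'
#' One id per line; `#` starts a comment; blank lines ignored.
#' @param path File path.
#' @return Character vector of ids.
#' @export
read_id_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Assemble transcript records
#'
#' Joins parsed coding sequences with annotation-derived 5'UTR attributes and
#' user-provided leader-class id lists (leader classes are inputs, not
#' predictions). Transcripts without an annotation row are dropped with a
#' message.
#'
#' @param cds_records Data.frame with `transcript_id`, `cds`.
#' @param annotations Output of [read_annotation_table()].
#' @param sscr_ids,mscr_ids Character vectors of transcript ids.
#' @return Data.frame of transcript records (one row per transcript) with
#'   columns `transcript_id`, `cds`, `utr5_length`, `utr5_intron_count`,
#'   `has_5ui`, `leader_class`, `non_utr5_intron_total`.
#' @export
build_transcript_records <- function(cds_records, annotations,
                                     sscr_ids = character(),
                                     mscr_ids = character()) {
  idx <- match(cds_records$transcript_id, annotations$transcript_id)
  if (anyNA(idx)) {
    message(sum(is.na(idx)), " transcript(s) without annotation dropped")
    cds_records <- cds_records[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  der <- lapply(idx, function(i) derive_utr5(annotations[i, ]))
  both <- intersect(sscr_ids, mscr_ids)
  if (length(both))
    warning("ids in both leader lists treated as SSCR: ",
            paste(utils::head(both, 3), collapse = ", "))
  out <- data.frame(
    transcript_id = cds_records$transcript_id,
    cds = cds_records$cds,
    utr5_length = vapply(der, `[[`, integer(1), "utr5_length"),
    utr5_intron_count = vapply(der, `[[`, integer(1), "utr5_intron_count"),
    stringsAsFactors = FALSE)
  out$has_5ui <- out$utr5_intron_count > 0L
  out$leader_class <- ifelse(out$transcript_id %in% sscr_ids, "SSCR",
                      ifelse(out$transcript_id %in% mscr_ids, "MSCR", "OTHER"))
  out$non_utr5_intron_total <-
    vapply(der, `[[`, numeric(1), "non_utr5_intron_total")
  out
}

#' Validate transcript-record invariants
#'
#' Checks the type contract of a filtered record set: CDS length a multiple
#' of 3 and at least 150 nt, `has_5ui` consistent with the intron count, and
#' a known leader class.
#'
#' @param records Transcript-record data.frame.
#' @return Invisibly `TRUE`; stops with a message otherwise.
#' @export
validate_transcript_records <- function(records) {
  len <- nchar(records$cds)
  if (any(len %% 3 != 0)) stop("CDS length not a multiple of 3")
  if (any(len < 150)) stop("CDS shorter than 150 nt")
  if (any(grepl("[^ACGT]", records$cds))) stop("CDS contains non-ACGT characters")
  if (any(records$utr5_length < 0)) stop("negative 5'UTR length")
  if (any(records$utr5_intron_count < 0)) stop("negative 5UI count")
  if (!all(records$has_5ui == (records$utr5_intron_count > 0)))
    stop("has_5ui inconsistent with utr5_intron_count")
  if (!all(records$leader_class %in% c("SSCR", "MSCR", "OTHER")))
    stop("unknown leader class")
  invisible(TRUE)
}
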