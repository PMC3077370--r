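# Redundancy reduction before motif analysis. The original analysis grouped
# near-identical sequences with blastn (E < 1e-25 on the first 99 nt); here
# the grouping is a documented dialect: exact-word seeding (blastn-like)
# followed by local alignment, linking pairs with >= min_identity over an
# aligned span >= min_overlap, then single-linkage components.

.prefix_word_candidates <- function(prefixes, word_size) {
  n <- length(prefixes)
  idx <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    L <- nchar(prefixes[i])
    if (L < word_size) next
    words <- unique(substring(prefixes[i], 1:(L - word_size + 1),
                              word_size:L))
    for (w in words) assign(w, c(get0(w, envir = idx), i), envir = idx)
  }
  pairs <- new.env(parent = emptyenv())
  for (w in ls(idx, sorted = FALSE)) {
    hits <- get(w, envir = idx)
    if (length(hits) < 2L) next
    for (a in seq_len(length(hits) - 1L))
      for (b in seq((a + 1L), length(hits))) {
        key <- paste(hits[a], hits[b])
        assign(key, TRUE, envir = pairs)
      }
  }
  keys <- ls(pairs, sorted = FALSE)
  if (!length(keys)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, lapply(strsplit(keys, " "), as.integer))
}

#' Cluster sequences by similarity of their first 99 nt
#'
#' Pairwise local alignment (match +1, mismatch -1, gap -2) of the first
#' 99-nt prefixes, forward strand only. Pairs reaching `min_identity` over an
#' aligned span of at least `min_overlap` nt are linked; clusters are the
#' single-linkage connected components. Candidate pairs are pre-selected by a
#' shared exact word of `word_size` nt, so unrelated sequences are never
#' aligned.
#'
#' @param records Data.frame with `transcript_id` and `cds` (each >= 99 nt).
#' @param min_identity Minimum fraction identity over the aligned span.
#' @param min_overlap Minimum aligned span in nt.
#' @param word_size Seed word length for candidate-pair detection.
#' @return List of clusters, each a list with `member_ids` and (initially
#'   `NA`) `representative_id`; class `similarity_clusters`.
#' @export
cluster_first99 <- function(records, min_identity = 0.9, min_overlap = 60L,
                            word_size = 10L) {
  len <- nchar(records$cds)
  if (any(len < 99))
    stop("CDS shorter than 99 nt: ",
         records$transcript_id[which(len < 99)[1]])
  prefixes <- substr(records$cds, 1, 99)
  n <- length(prefixes)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  cand <- .prefix_word_candidates(prefixes, word_size)
  if (nrow(cand)) {
    submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (find(i) == find(j)) next
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(prefixes[i]), Biostrings::DNAString(prefixes[j]),
        type = "local", substitutionMatrix = submat,
        gapOpening = 0, gapExtension = 2)
      span <- nchar(as.character(Biostrings::pattern(aln)))
      ident <- if (span > 0) Biostrings::nmatch(aln) / span else 0
      if (span >= min_overlap && ident >= min_identity) {
        parent[find(i)] <- find(j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(seq_len(n), roots)
  clusters <- lapply(unname(comps), function(ix)
    list(member_ids = records$transcript_id[ix],
         representative_id = NA_character_))
  structure(clusters, class = "similarity_clusters")
}

#' Pick one random representative per cluster
#'
#' @param clusters Output of [cluster_first99()].
#' @param seed Integer seed; deterministic per seed.
#' @return The clusters with `representative_id` filled in.
#' @export
pick_representatives <- function(clusters, seed = 1L) {
  out <- withr::with_seed(seed, {
    lapply(clusters, function(cl) {
      ids <- cl$member_ids
      cl$representative_id <-
        if (length(ids) == 1L) ids else ids[sample.int(length(ids), 1L)]
      cl
    })
  })
  structure(out, class = "similarity_clusters")
}

#' Subset records to cluster representatives
#'
#' @param records Data.frame with `transcript_id`.
#' @param clusters Clusters with representatives assigned.
#' @return Subset of `records`.
#' @export
representative_records <- function(records, clusters) {
  reps <- vapply(clusters, `[[`, character(1), "representative_id")
  if (anyNA(reps)) stop("clusters have unassigned representatives")
  records[records$transcript_id %in% reps, , drop = FALSE]
}

#' Write a TSV cluster report
#'
#' Columns: `cluster_id`, `representative_id`, `member_count`, `member_ids`
#' (comma-separated).
#' @param clusters Clusters with representatives assigned.
#' @param path Output file.
#' @export
write_cluster_report <- function(clusters, path) {
  df <- data.frame(
    cluster_id = sprintf("C%04d", seq_along(clusters)),
    representative_id = vapply(clusters, `[[`, character(1),
                               "representative_id"),
    member_count = vapply(clusters, function(cl) length(cl$member_ids),
                          integer(1)),
    member_ids = vapply(clusters, function(cl)
      paste(cl$member_ids, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
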