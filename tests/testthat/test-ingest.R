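# FASTA/annotation ingest, 5'UTR derivation, CDS filters, dedup.

write_fasta_text <- function(ids, seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

`%+%` <- function(a, b) paste0(a, b)

test_that("FASTA parsing keeps valid records and rejects bad alphabets", {
  p <- write_fasta_text(c("tx1", "tx2"),
                        c(strrep("ACG", 50), strrep("ACGT", 38) %+% "A"))
  out <- parse_cds_fasta(p)
  expect_equal(nrow(out$records), 2)
  expect_equal(nchar(out$records$cds), c(150, 153))

  p2 <- write_fasta_text(c("ok", "rna"), c(strrep("ACGT", 40), "ACGU"))
  out2 <- parse_cds_fasta(p2)
  expect_equal(nrow(out2$rejects), 1)
  expect_equal(out2$rejects$reason, "invalid alphabet")

  p3 <- write_fasta_text(c("hasN"), c("ACGTNACGT"))
  expect_equal(parse_cds_fasta(p3)$rejects$reason, "contains N")

  p4 <- write_fasta_text(c("dup", "dup"), c("ACGT", "ACGT"))
  expect_error(parse_cds_fasta(p4), "dup")
})

`%+%` <- function(a, b) paste0(a, b)

test_that("FASTA write/parse round-trips 50 random records", {
  set.seed(21)
  rec <- data.frame(
    transcript_id = sprintf("R%03d", 1:50),
    cds = vapply(1:50, function(i) rand_seq(3 * sample(50:120, 1)),
                 character(1)),
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".fa")
  write_cds_fasta(rec, path)
  back <- parse_cds_fasta(path)
  expect_equal(back$records$transcript_id, rec$transcript_id)
  expect_equal(back$records$cds, rec$cds)
  expect_equal(nrow(back$rejects), 0)
})

ann_row <- function(strand, starts, ends, cds_start, cds_end) {
  list(strand = strand, exon_starts = starts, exon_ends = ends,
       cds_start = cds_start, cds_end = cds_end)
}

test_that("5'UTR derivation follows transcript orientation", {
  # single exon, CDS 30 nt in
  d <- derive_utr5(ann_row("+", 0, 500, 30, 480))
  expect_equal(d$utr5_length, 30L)
  expect_equal(d$utr5_intron_count, 0L)

  # plus strand: exon1 = 100 nt UTR, intron, exon2 = 20 UTR nt then CDS
  d2 <- derive_utr5(ann_row("+", c(0, 300), c(100, 800), 320, 700))
  expect_equal(d2$utr5_length, 120L)
  expect_equal(d2$utr5_intron_count, 1L)
  expect_equal(d2$non_utr5_intron_total, 0)

  # minus-strand mirror of the same structure (chromosome length 1000):
  # exon [900,1000) is the 100-nt UTR exon, exon [200,700) starts with 20
  # UTR nt (from the right) then CDS
  d3 <- derive_utr5(ann_row("-", c(200, 900), c(700, 1000), 300, 680))
  expect_equal(d3$utr5_length, 120L)
  expect_equal(d3$utr5_intron_count, 1L)

  # CDS start outside exons
  expect_error(derive_utr5(ann_row("+", c(0, 300), c(100, 800), 150, 700)),
               "inconsistent annotation")
})

test_that("strand symmetry: mirrored annotations give identical outputs", {
  set.seed(17)
  for (rep in 1:20) {
    n_ex <- sample(1:4, 1)
    lens <- sample(50:300, n_ex, replace = TRUE)
    gaps <- if (n_ex > 1) sample(100:500, n_ex - 1, replace = TRUE) else integer(0)
    starts <- cumsum(c(100, if (n_ex > 1) lens[-n_ex] + gaps else numeric(0)))
    ends <- starts + lens
    total <- sum(lens)
    cds_off <- sample(0:(total - 10), 1)
    # map transcript offset -> genomic (+)
    cum <- cumsum(c(0, lens))
    ei <- findInterval(cds_off, cum, left.open = FALSE)
    g_start <- starts[ei] + (cds_off - cum[ei])
    g_end <- ends[n_ex] - 1
    dp <- derive_utr5(ann_row("+", starts, ends, g_start, g_end + 1))
    C <- 10000
    dm <- derive_utr5(ann_row("-", rev(C - ends), rev(C - starts),
                              C - (g_end + 1), C - g_start))
    expect_identical(dp, dm)
  }
})

test_that("CDS filters remove and count by rule, first rule wins", {
  rec <- data.frame(transcript_id = c("a", "b", "c", "d"),
                    cds = c(strrep("A", 149), strrep("C", 150),
                            strrep("G", 151), strrep("T", 300)),
                    stringsAsFactors = FALSE)
  out <- apply_cds_filters(rec)
  expect_equal(out$records$transcript_id, c("b", "d"))
  # 149 fails both rules and is attributed to the first-checked one; 151 is
  # out of frame only. Both land under not_multiple_of_3.
  expect_equal(unname(out$report), c(2, 0))

  rec2 <- data.frame(transcript_id = c("x", "y"),
                     cds = c(strrep("ACG", 40), strrep("ACG", 60)),
                     stringsAsFactors = FALSE)
  out2 <- apply_cds_filters(rec2)
  expect_equal(nrow(out2$records), 1)          # 120 nt is in-frame but short
  expect_equal(unname(out2$report), c(0, 1))

  # idempotence
  again <- apply_cds_filters(out$records)
  expect_identical(again$records, out$records)
  expect_equal(sum(again$report), 0)
})

test_that("filter report matches generator-side bookkeeping on random input", {
  set.seed(33)
  n <- 500
  lens <- sample(c(sample(seq(150, 600, by = 3), 350, replace = TRUE),
                   sample(c(149, 151, 200, 250), 100, replace = TRUE),
                   sample(seq(60, 147, by = 3), 50, replace = TRUE)))
  rec <- data.frame(transcript_id = sprintf("g%03d", 1:n),
                    cds = vapply(lens, function(L)
                      strrep("A", L), character(1)),
                    stringsAsFactors = FALSE)
  expected_not3 <- sum(lens %% 3 != 0)
  expected_short <- sum(lens %% 3 == 0 & lens < 150)
  out <- apply_cds_filters(rec)
  expect_equal(unname(out$report["not_multiple_of_3"]), expected_not3)
  expect_equal(unname(out$report["too_short"]), expected_short)
  expect_equal(nrow(out$records), n - expected_not3 - expected_short)
})

test_that("splice-variant dedup groups by leader identity, deterministically", {
  set.seed(2)
  shared <- rand_seq(69)
  rec <- data.frame(
    transcript_id = c("v1", "v2", "v3", "solo"),
    cds = c(paste0(shared, rand_seq(120)), paste0(shared, rand_seq(120)),
            paste0(shared, rand_seq(120)), rand_seq(189)),
    stringsAsFactors = FALSE)
  out <- dedup_splice_variants(rec, "identical_leader69", seed = 5)
  expect_equal(nrow(out), 2)
  out2 <- dedup_splice_variants(rec, "identical_leader69", seed = 5)
  expect_identical(out$transcript_id, out2$transcript_id)
})

test_that("dedup representative choice is uniform across seeds", {
  set.seed(8)
  shared <- replicate(50, rand_seq(69))
  rec <- data.frame(
    transcript_id = sprintf("p%03d", 1:100),
    cds = paste0(rep(shared, each = 2),
                 replicate(100, rand_seq(120))),
    stringsAsFactors = FALSE)
  picks <- vapply(1:200, function(s) {
    out <- dedup_splice_variants(rec, "identical_leader69", seed = s)
    # fraction of groups whose first member was chosen
    mean(as.integer(sub("p", "", out$transcript_id)) %% 2 == 1)
  }, numeric(1))
  frac <- mean(picks)
  n_draws <- 200 * 50
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_draws))
})

test_that("transcript assembly derives 5UI status and validates", {
  cfg <- synthetic_config(n_pos = 25, n_neg = 25, seed = 12)
  d <- gen_dataset(cfg)
  dir <- tempfile(); paths <- write_dataset(d, dir)
  parsed <- parse_cds_fasta(paths[["fasta"]])
  ann <- read_annotation_table(paths[["annotation"]])
  sscr <- read_id_list(paths[["sscr"]])
  rec <- build_transcript_records(parsed$records, ann, sscr_ids = sscr)
  expect_equal(nrow(rec), 50)
  expect_identical(rec$has_5ui[match(d$records$transcript_id,
                                     rec$transcript_id)],
                   d$records$has_5ui)
  expect_true(validate_transcript_records(rec))
  expect_true(all(rec$leader_class == "SSCR"))
})
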