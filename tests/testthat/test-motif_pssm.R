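# PSSM construction, scanning, overlap disambiguation, t*, occurrences,
# and the exhaustive degenerate k-mer scan.

test_that("PSSM construction from sites follows the pseudocount formula", {
  p <- pssm_from_sites(rep("CGCCGC", 10), pseudocount = 0)
  expect_true(all(apply(p$probs, 2, max) == 1))
  expect_equal(unname(p$probs["C", 1]), 1)

  p2 <- pssm_from_sites(c("CGCG", "CGGC"), pseudocount = 0)
  expect_equal(unname(p2$probs[, 3]), c(0, 0.5, 0.5, 0))

  # pseudocount 0.5, 4 sites: column with 3 C and 1 G
  p3 <- pssm_from_sites(c("CAAA", "CAAA", "CAAA", "GAAA"), pseudocount = 0.5)
  expect_equal(unname(p3$probs[, 1]),
               c(0.5, 3.5, 1.5, 0.5) / 6, tolerance = 1e-12)

  expect_error(pssm_from_sites(c("ACGT", "ACG")), "identical lengths")
  expect_error(new_pssm(matrix(1, 4, 6)), "sum to 1")
})

test_that("PSSM simple and MEME formats round-trip", {
  p <- consensus_pssm("CGSSGC")
  f <- tempfile()
  write_pssm(p, f)
  back <- read_pssm(f, format = "simple")
  expect_equal(back$probs, p$probs, tolerance = 1e-12)

  meme <- c("MEME version 4", "", "ALPHABET= ACGT", "",
            "Background letter frequencies",
            "A 0.2 C 0.3 G 0.3 T 0.2", "",
            "MOTIF CGSSGC", "letter-probability matrix: alength= 4 w= 6 nsites= 4",
            apply(t(p$probs), 1, function(r) paste(sprintf("%.6f", r),
                                                   collapse = " ")))
  fm <- tempfile()
  writeLines(meme, fm)
  bm <- read_pssm(fm)
  expect_equal(unname(bm$probs), unname(p$probs), tolerance = 1e-04)
  expect_equal(unname(bm$background), c(0.2, 0.3, 0.3, 0.2))
  expect_equal(bm$name, "CGSSGC")
})

test_that("scanning retains the best window of an overlap run", {
  # indicator PSSM for ACGT: only the exact match scores high
  ind <- new_pssm(diag(4)[, ], name = "ind")
  # place ACGT at offset 12 in an otherwise ACGT-free context
  s <- paste0(strrep("CCG", 4), "ACGT", strrep("GGC", 20))
  h <- scan_sequence(ind, s, region = nchar(s))
  best <- h[which.max(h$score), ]
  expect_equal(best$position, 12)
  # windows overlapping the retained one are suppressed
  expect_false(any(abs(h$position - 12) < 4 & h$position != 12))

  # crafted three-window case: scores (5, 7, 6) -> middle survives
  scores <- c(5, 7, 6)
  kept <- alrexscan:::.nms_retain(scores, width = 3)
  expect_equal(kept, 2L)
})

test_that("scan equals the brute-force reference on random instances", {
  set.seed(23)
  for (rep in 1:50) {
    w <- sample(4:8, 1)
    pssm <- rand_test_pssm(w)
    s <- rand_seq(sample(60:120, 1))
    h <- scan_sequence(pssm, s, region = min(99, nchar(s)))
    b <- brute_scan(pssm, s, region = 99)
    expect_equal(h$position, b$position)
    expect_equal(h$score, b$score, tolerance = 1e-10)
    # retained hits never mutually overlap
    if (nrow(h) > 1) expect_true(all(diff(sort(h$position)) >= w))
    expect_equal(h$frame, h$position %% 3)
  }
})

test_that("t* selection minimizes the enrichment p over all candidates", {
  # perfect separation: t* at the smallest positive-group maximum
  pos <- c(5, 6, 7, 8); neg <- c(1, 2, 3, 4)
  sel <- select_threshold_tstar(pos, neg)
  expect_equal(sel$t_star, 5)
  expect_equal(sel$fisher_p,
               oracle_hyper_tail(8, 4, 4, 4, "greater"), tolerance = 1e-12)

  # identical score lists: no discrimination anywhere; the tie on the
  # minimal greater-tail p (0.8 at both t=2 and t=3 here) resolves to the
  # most stringent candidate
  sel2 <- select_threshold_tstar(c(1, 2, 3), c(1, 2, 3))
  expect_equal(sel2$fisher_p, oracle_hyper_tail(6, 3, 4, 2, "greater"),
               tolerance = 1e-12)
  expect_equal(sel2$t_star, 3)

  set.seed(31)
  for (rep in 1:10) {
    pos <- round(rnorm(40, 1), 2); neg <- round(rnorm(40), 2)
    sel <- select_threshold_tstar(pos, neg)
    br <- brute_tstar(pos, neg)
    expect_equal(sel$t_star, br$t_star)
    expect_equal(sel$fisher_p, br$p, tolerance = 1e-10)
  }
})

test_that("occurrence statistics count presence, multiplicity, frame, position", {
  hits <- data.frame(transcript_id = c("a", "a", "b", "c", "c", "d"),
                     position = c(0, 6, 3, 9, 30, 12),
                     frame = c(0, 0, 0, 0, 0, 0),
                     score = c(9, 8, 9, 9, 7, 2))
  labels <- c(a = FALSE, b = FALSE, e = FALSE, c = TRUE, d = TRUE, f = TRUE)
  occ <- occurrence_stats(hits, labels, threshold = 5)
  gm <- occ$group_5ui_minus; gp <- occ$group_5ui_plus
  expect_equal(gm$n_sequences, 3)
  expect_equal(gm$frac_ge1, 2 / 3)
  expect_equal(gm$frac_ge2, 1 / 3)
  expect_equal(gp$frac_ge1, 1 / 3)   # d's hit is below threshold
  expect_equal(gp$frac_ge2, 1 / 3)   # both of c's hits clear the threshold
  # all hits codon-aligned -> frame 0 fraction 1
  expect_equal(gm$frame_fractions[1], 1)
  expect_equal(gm$median_position_1based, stats::median(c(0, 6, 3)) + 1)

  # empty hit set: explicit zero counts, no test p-values
  occ0 <- occurrence_stats(hits[0, ], labels, threshold = 5)
  expect_equal(occ0$group_5ui_minus$n_occurrences, 0)
  expect_true(is.na(occ0$group_5ui_minus$frame_chisq_p))
  expect_null(occ0$position_test)
})

test_that("degenerate k-mer scan: degenerate cases and planted recovery", {
  set.seed(41)
  seqs <- vapply(1:30, function(i) rand_seq(99), character(1))
  same <- discriminative_kmer_scan(seqs, seqs, k = 3,
                                   alphabet = c("A", "C", "G", "T"))
  # identical sets: every overlap sits exactly at its null expectation, so
  # no k-mer approaches significance (the greater tail at the proportional
  # split is bounded well away from 0) and nothing survives Bonferroni
  expect_true(all(same$p_raw > 0.45))
  expect_true(all(same$p_bonferroni == 1))
  expect_error(discriminative_kmer_scan(seqs, seqs, k = 9), "refused")

  # plant CGSSGC in half the positive set only
  plant <- function(s, frac) {
    n <- length(s)
    idx <- sample(n, round(frac * n))
    for (i in idx) {
      inst <- paste0("CG", paste(sample(c("C", "G"), 2, TRUE), collapse = ""),
                     "GC")
      pos <- sample(1:90, 1)
      substr(s[i], pos, pos + 5) <- inst
    }
    s
  }
  pos <- plant(vapply(1:80, function(i) rand_seq(99), character(1)), 0.6)
  neg <- vapply(1:80, function(i) rand_seq(99), character(1))
  res <- discriminative_kmer_scan(pos, neg, k = 6, top = 5)
  spec_of <- function(km) {
    ref <- strsplit("CGSSGC", "")[[1]]
    x <- strsplit(km, "")[[1]]
    all(mapply(function(r, b) {
      if (r == "S") b %in% c("C", "G", "S") else b == r
    }, ref, x))
  }
  expect_true(any(vapply(res$kmer, spec_of, logical(1))))
})

test_that("k-mer scan finds nothing significant on label-shuffled data", {
  set.seed(47)
  base <- vapply(1:60, function(i) rand_seq(99), character(1))
  n_pass <- 0
  for (shuf in 1:10) {
    idx <- sample(60, 30)
    res <- discriminative_kmer_scan(base[idx], base[-idx], k = 4,
                                    alphabet = c("A", "C", "G", "T", "S", "W"))
    if (min(res$p_bonferroni) >= 0.05) n_pass <- n_pass + 1
  }
  expect_gte(n_pass, 9)
})
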