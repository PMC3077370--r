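# 69-nt leader-window composition statistics.

test_that("CDS partition splits at nucleotide 69 and round-trips", {
  p <- partition_cds(strrep("ACG", 50))
  expect_equal(nchar(p$first69), 69)
  expect_equal(nchar(p$rest), 81)
  p2 <- partition_cds(strrep("ACGT", 75))
  expect_equal(nchar(p2$first69), 69)
  expect_equal(nchar(p2$rest), 231)
  set.seed(4)
  for (i in 1:20) {
    cds <- rand_seq(3 * sample(50:150, 1))
    pp <- partition_cds(cds)
    expect_identical(paste0(pp$first69, pp$rest), cds)
  }
  expect_error(partition_cds(strrep("A", 100)), "multiple of 3")
})

test_that("codon feature counting matches direct codon-table logic", {
  # ATG CTG CTG: M, L, L; one adenine; CTG is adenine-lacking, M not in set
  fv <- codon_feature_vector("ATGCTGCTG")
  expect_equal(fv$adenine_count, 1)
  expect_equal(fv$adenine_percent, 100 / 9, tolerance = 1e-12)
  expect_equal(fv$aa_counts[["L"]], 2)
  expect_equal(fv$aa_counts[["I"]], 0)
  expect_equal(fv$adenineless_codons, 2)
  expect_equal(fv$adenineful_codons, 0)

  # TTA AGC: L and S both in the seven, both codons contain an A
  fv2 <- codon_feature_vector("TTAAGC")
  expect_equal(fv2$adenineless_codons, 0)
  expect_equal(fv2$adenineful_codons, 2)

  # GCT GCA: alanine twice; GCA lacks T, GCT contains it
  fv3 <- codon_feature_vector("GCTGCA")
  expect_equal(fv3$thymineless_codons, 1)
  expect_equal(fv3$thymineful_codons, 1)

  expect_error(codon_feature_vector("ACGTA"), "multiple of 3")
  expect_error(codon_feature_vector("ACGTNA"), "ambiguous")
})

test_that("codon-class membership agrees with an independent 64-codon oracle", {
  # oracle: enumerate A-membership of all codons independently
  codons <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
  gc_map <- Biostrings::GENETIC_CODE
  set.seed(9)
  for (rep in 1:15) {
    cds <- rand_seq(3 * sample(30:60, 1))
    fv <- codon_feature_vector(cds)
    cd <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    aa <- unname(gc_map[cd])
    seven <- aa %in% c("L", "V", "A", "P", "S", "G", "R")
    nine <- aa %in% c("A", "T", "P", "H", "N", "D", "R", "S", "G")
    expect_equal(fv$adenineless_codons, sum(seven & !grepl("A", cd)))
    expect_equal(fv$adenineful_codons, sum(seven & grepl("A", cd)))
    expect_equal(fv$thymineless_codons, sum(nine & !grepl("T", cd)))
    expect_equal(fv$thymineful_codons, sum(nine & grepl("T", cd)))
    # class sums cover exactly the codons of the listed amino acids
    expect_equal(fv$adenineless_codons + fv$adenineful_codons, sum(seven))
    expect_equal(fv$thymineless_codons + fv$thymineful_codons, sum(nine))
    # window additivity of adenine counts
    if (nchar(cds) >= 150) {
      parts <- partition_cds(cds)
      expect_equal(codon_feature_vector(parts$first69)$adenine_count +
                     codon_feature_vector(parts$rest, "rest")$adenine_count,
                   fv$adenine_count)
    }
  }
})

test_that("feature extraction is invariant to codon-identity-preserving shuffles", {
  set.seed(14)
  cds <- rand_seq(120)
  cd <- substring(cds, seq(1, 120, 3), seq(3, 120, 3))
  shuffled <- paste(sample(cd), collapse = "")
  a <- codon_feature_vector(cds); b <- codon_feature_vector(shuffled)
  for (f in c("adenine_count", "adenineless_codons", "adenineful_codons",
              "thymineless_codons", "thymineful_codons"))
    expect_equal(a[[f]], b[[f]])
  expect_equal(a$aa_counts, b$aa_counts)
})

test_that("group comparison: identity gives OR 1 / p 1; pooled counts drive OR", {
  set.seed(6)
  g <- lapply(1:12, function(i) codon_feature_vector(rand_seq(69)))
  same <- compare_groups(g, g, "leu_ile")
  expect_equal(same$test$effect, 1, tolerance = 1e-12)
  expect_equal(same$test$p_value, 1)

  # synthetic pooled counts (L1=400, I1=100) vs (L2=200, I2=200) -> OR 4
  mk <- function(L, I) {
    structure(list(aa_counts = c(L = L, I = I, R = 0, K = 0)),
              class = "codon_features")
  }
  cmp <- compare_groups(list(mk(400, 100)), list(mk(200, 200)), "leu_ile")
  expect_equal(cmp$test$effect, 4)
  expect_equal(cmp$test$p_value,
               oracle_fisher_two_sided(900, 500, 600, 400), tolerance = 1e-09)
})

test_that("adenine comparison reports medians, bootstrap SEs and relative difference", {
  set.seed(19)
  g1 <- lapply(1:60, function(i)
    codon_feature_vector(rand_seq(69, probs = c(0.15, 0.3, 0.3, 0.25))))
  g2 <- lapply(1:60, function(i)
    codon_feature_vector(rand_seq(69, probs = c(0.3, 0.23, 0.23, 0.24))))
  cmp <- compare_groups(g1, g2, "adenine_percent", B = 300, seed = 3)
  expect_lt(cmp$median_group1, cmp$median_group2)
  expect_gt(cmp$relative_median_difference, 0)
  expect_gt(cmp$median_se_group1, 0)
  expect_lt(cmp$test$p_value, 0.01)
  expect_equal(length(cmp$relative_median_difference_ci), 2)
})
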