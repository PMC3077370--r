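# alrexscan

Coding-region motif and codon-bias analysis by 5'UTR intron status.

## What this package is for

Transcripts encoding secreted and mitochondrial proteins carry nucleotide
elements at the 5' end of their coding regions — inside the
signal-sequence coding region (SSCR) or the mitochondrial-targeting
sequence coding region (MSCR) — that can drive an alternative,
splicing-independent mRNA nuclear export route (ALREX). Under a
first-element-wins model, a gene whose 5'UTR contains an intron (a 5UI)
is exported by the splicing-dependent route, and selection on its
ALREX-promoting sequence features relaxes. The measurable consequence is
a set of contrasts between 5UI-lacking (5UI−) and 5UI-containing (5UI+)
genes in the first 69 nt of the ORF: adenine depletion, preference for
leucine over isoleucine and arginine over lysine, a bias towards
adenine- and thymine-lacking synonymous codons, and enrichment of a
GC-rich degenerate motif (consensus `CGSSGC`, S = C/G) that occurs more
often, in more copies, and closer to the 5' end in 5UI− genes.

`alrexscan` implements that analysis as a tested, reusable R pipeline for
computational biologists: annotation ingest and 5UI derivation,
redundancy clustering, the 69-nt codon statistics, PSSM scanning with
overlap disambiguation and enrichment-optimal thresholds, a Dirichlet
random-PSSM ROC null model, resampling-corrected category enrichment with
a 5'UTR-length-stratified control, and a calibrated synthetic-data
generator so the whole pipeline runs and is validated without
genome-scale inputs.

## The statistics at the core

For a motif score threshold *t*, sequences are classified motif-containing
when their maximum PSSM window score (log2 odds against the background,
within the first 99 nt, overlapping windows collapsed to the best one) is
at least *t*. With *N* sequences, *m* in the 5UI− class, *n*
motif-containing and *k* overlapping, the enrichment probability is the
hypergeometric tail

P(X ≥ k) = Σᵢ₌ₖ C(m, i) · C(N−m, n−i) / C(N, n),

and *t\** is the threshold minimizing it. Motif quality is judged
competitively: random PSSMs with columns drawn from a Dirichlet
distribution with concentration equal to the background base frequencies
(Σα = 1) are scanned identically, ROC curves (TPR = motif-containing
fraction of 5UI−, FPR = same for 5UI+) are compared at fixed FPRs, and a
motif's percentile is the fraction of null motifs it beats. Category
enrichment is ranked by LOD (log10 odds ratio) with a min-p
label-resampling adjustment that preserves the dependence among
overlapping terms.

## A worked example

Generate a labeled dataset at its default planted effect sizes (scaled to
500 sequences per class), recover the adenine contrast, select *t\**, and
rank the planted motif against the Dirichlet null:

```r
library(alrexscan)

cfg <- synthetic_config(n_pos = 500, n_neg = 500, seed = 42)
d   <- gen_dataset(cfg)
rec <- d$records

fv  <- lapply(rec$cds, function(s) codon_feature_vector(partition_cds(s)$first69))
cmp <- compare_groups(fv[!rec$has_5ui], fv[rec$has_5ui], "adenine_percent", seed = 1)
cat(sprintf("medians %.2f%% vs %.2f%%, relative difference %.1f%%\n",
            cmp$median_group1, cmp$median_group2,
            100 * cmp$relative_median_difference))
#> medians 13.04% vs 15.94%, relative difference 18.2%
cmp$test
#> Wilcoxon rank-sum (normal approx)
#>   statistic = 78873, p (two_sided) = 3.396e-24

bg   <- sequence_background(rec$cds)
pssm <- pssm_from_sites(d$truth$instance, background = bg, name = "CGSSGC")
hits <- scan_transcripts(pssm, rec)
maxima <- tapply(hits$score, factor(hits$transcript_id, levels = rec$transcript_id), max)
sel  <- select_threshold_tstar(maxima[!rec$has_5ui], maxima[rec$has_5ui])
cat(sprintf("t* = %.2f bits, greater-tail p = %.3g\n", sel$t_star, sel$fisher_p))
#> t* = 8.87 bits, greater-tail p = 1.45e-17

rank_against_null(pssm, rec$cds[!rec$has_5ui], rec$cds[rec$has_5ui],
                  n_null = 200, seed = 1, background = bg)
#>  fpr target_tpr null_median_tpr percentile
#>  0.1      0.248           0.080          1
#>  0.2      0.430           0.182          1
#>  ...
#>  0.7      0.880           0.686          1
#> min percentile over grid: 1.0000 (n_null = 200)
```

The adenine medians (13.0% vs 15.9%) recover the configured 18.2%
relative depletion; *t\** separates 215/500 5UI− from 92/500 5UI+
sequences at the planted presence fractions; and the planted-site PSSM
outperforms every one of 200 random motifs across the FPR range 0.1–0.7.

The full pipeline — simulate, ingest from disk, cluster, codon features,
motif scan, null ranking, enrichment — runs from one configuration:

```r
manifest <- run_pipeline(default_config(profile = "test",
                                        outdir = "alrex_run", seed = 1))
```

or from a shell via the thin wrapper `inst/scripts/alrexscan.R`.

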