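---
title: "Methods: coding-region motif and codon-bias analysis by 5'UTR intron status"
author: "alrexscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coding-region motif and codon-bias analysis by 5'UTR intron status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alrexscan)
```

## The scientific question

Most spliced mRNAs in higher eukaryotes are exported from the nucleus by
factors deposited near the 5' cap during splicing. Transcripts encoding
secreted and mitochondrial proteins can instead use an alternative export
route (ALREX) promoted by nucleotide elements inside the signal-sequence
coding region (SSCR) or the mitochondrial-targeting sequence coding region
(MSCR) — the first ~69 nt of the open reading frame. Under a
"first-element-wins" model, a transcript whose 5'UTR contains an intron
(a 5UI) is committed to the splicing-dependent route before its SSCR/MSCR
is even transcribed, so selection maintaining ALREX-promoting nucleotide
features should relax in 5UI-containing genes.

`alrexscan` implements the computational side of that analysis as a
reusable pipeline:

* derivation of 5UI status and 5'UTR length from refGene-like annotation
  tables, with the CDS filters and splice-variant deduplication applied to
  the coding sequences;
* similarity clustering of the first 99 nt to avoid over-weighting
  near-duplicate genes;
* codon-composition statistics of the first 69 nt versus the rest of the
  ORF: adenine content, leucine:isoleucine and arginine:lysine preferences,
  and the adenine-lacking / thymine-lacking synonymous codon classes;
* PSSM scanning of the first 99 nt with overlap disambiguation, an
  enrichment-optimal score threshold (t\*), occurrence statistics
  (presence, multiplicity, reading frame, position), and an exhaustive
  degenerate k-mer scan as a simple built-in discriminative finder;
* a Dirichlet random-PSSM null model with ROC ranking and a
  null-calibrated threshold (t');
* category (GO-style) enrichment of 5UI status with LOD ranking, a min-p
  label-resampling multiplicity adjustment, and a 5'UTR-length-stratified
  (Cochran–Mantel–Haenszel) control;
* a calibrated synthetic-data generator that reproduces the statistical
  structure the analysis assumes, so every stage runs and is validated
  without genome-scale downloads.

## Ingest and annotation conventions

Coordinates are 0-based half-open throughout (UCSC table convention);
human-facing outputs report 1-based positions and label them as such.
The 5'UTR length is the total exonic length strictly 5' of the CDS start
in transcript orientation, on either strand; the 5UI count is the number
of introns lying wholly 5' of the CDS start. An intron at the exact
UTR/CDS junction counts as a 5UI because it is entirely upstream of the
CDS. Coding sequences whose length is not a multiple of three are removed
first, then those shorter than 150 nt; a sequence failing both rules is
counted once, under the first. Records containing `N` or other ambiguity
codes are rejected whole — the downstream codon and motif statistics are
not defined on ambiguous bases. Splice variants are collapsed to one
seeded-random representative per group, keyed either by the first 69 CDS
nt or by the 5'UTR splicing pattern.

Leader classes (SSCR / MSCR / OTHER) are user-supplied id lists, not
predictions: the upstream biology (signal-peptide and mitochondrial-leader
annotation) is taken as input, exactly as precomputed annotation databases
were used in the original analyses of this kind.

## Redundancy clustering

Closely related genes would otherwise dominate motif statistics. The
package clusters the first 99 nt of each CDS by local alignment (match +1,
mismatch −1, gap −2), linking pairs with at least 90% identity over an
aligned span of at least 60 nt, and takes single-linkage components with
one seeded-random representative each. Candidate pairs are pre-selected by
a shared exact 10-nt word, the same seeding idea BLAST uses; unrelated
sequences are never aligned. The thresholds are a documented dialect:
E-value-based grouping depends on database size and an external binary,
whereas an identity/overlap rule is self-contained and merges only
near-duplicates. The clustering is forward-strand only.

## The 69-nt window statistics

The first 69 nt of the CDS (the leader window: the initiator ATG plus 22
codons) are compared with the rest of the ORF. Per sequence the package
counts adenines, amino acids, and two codon classes: "adenine-lacking"
codons — codons containing no A at any of their three positions — over the
seven amino acids that possess both adenine-lacking and adenine-containing
codons (L, V, A, P, S, G, R), and the analogous "thymine-lacking" class
over its nine amino acids (A, T, P, H, N, D, R, S, G). Stop codons are
excluded from amino-acid tallies.

Group comparisons follow the statistic that each quantity supports:

* adenine percentage — Wilcoxon rank-sum on per-sequence values, plus
  group medians with bootstrap standard errors and the relative median
  difference `(med2 − med1)/med2` with a bootstrap SE;
* paired amino-acid preferences (L:I, R:K) and the codon-class ratios —
  Fisher's exact test on the pooled counts, which is the only presentation
  that yields odds ratios with Woolf confidence intervals; the per-gene
  mean ratio is also reported, with genes lacking the denominator amino
  acid dropped and counted.

## The exact 2x2 machinery

The motif-threshold selection rests on the hypergeometric tail: given `N`
sequences of which `m` are in the positive class and `n` are
motif-containing, the probability of observing `k` or more overlaps is the
sum of the hypergeometric pmf from `k` upwards. `hypergeom_tail()`
implements that sum directly in log-gamma arithmetic. `fisher_exact_2x2()`
builds on the same pmf: one-sided p-values are tail sums, the two-sided
p-value follows the pmf-ordering rule of mainstream statistical software
(sum over tables no more likely than the observed one), the effect is the
sample odds ratio `ad/bc`, and its 95% CI is the Woolf log-OR interval
with a Haldane +0.5 correction applied only when a cell is zero. A zero
margin returns p = 1 with a missing effect rather than an error. The test
suite checks both functions against a binomial-coefficient enumeration
oracle exhaustively for all tables with `N ≤ 50`.

One caveat worth knowing: under the greater-tail formula the p-value at a
perfectly proportional overlap is not 1 but a value bounded away from both
0 and 1, so "no discrimination" configurations yield p-values around
0.5–0.8 rather than exactly 1.

## Motif scanning and threshold selection

PSSM columns are `(count + pseudocount)/(n_sites + 4·pseudocount)` with a
default pseudocount of 0.5 — small enough to preserve the observed
preferences, large enough that unseen bases carry a finite penalty.
Windows within the first 99 nt (chosen so entire signal peptides are
covered) are scored as summed log2 odds against the background; with this
scale a Dirichlet-null motif (whose expected column equals the background)
scores near zero on background sequence, a convenient calibration.

Overlapping windows are disambiguated by greedy non-maximum suppression in
descending score order (ties to the leftmost window): among mutually
overlapping windows only the best survives, and retained hits never
overlap. Scanning is threshold-free; thresholds are applied downstream so
one scan serves both the t\* and t' analyses, and multiplicity counting
uses the thresholded retained set.

The enrichment-optimal threshold t\* sweeps the distinct observed
per-sequence maxima; at each candidate, sequences with maximum score at or
above it are "motif-containing", and the greater-tail hypergeometric
probability of the resulting 2x2 table is computed. The minimizing
threshold is returned, ties resolved towards the more stringent candidate.
The classification rule is `score ≥ t` everywhere.

The built-in discriminative finder enumerates every degenerate k-mer over
A/C/G/T/S/W (S = C/G, W = A/T), ranks by the greater-tail hypergeometric
p of presence in the positive versus negative set, and Bonferroni-adjusts
over the enumeration size. It is deliberately simple — an exhaustive,
reproducible stand-in for external discriminative motif finders, not a
replacement for them — and refuses k > 8 as a combinatorial guard.

## The Dirichlet null and ROC ranking

Random PSSM columns are independent Dirichlet draws with concentration
vector equal to the background base frequencies, so the total
concentration is 1: draws are sparse and peaked, which is the behaviour
wanted from a competitive null of "random motifs" rather than flat ones.
The background is the empirical composition of the pooled first 99 nt of
the analyzed sequences.

For every motif the ROC sweeps thresholds over the observed per-sequence
maxima; TPR is the motif-containing fraction of the 5UI− set and FPR the
same fraction of the 5UI+ set. TPR at a grid FPR uses step interpolation:
the TPR at the smallest threshold whose FPR does not exceed the grid
value. A target motif's percentile at a grid point is the fraction of null
motifs with TPR strictly below the target's; the minimum percentile over
the grid summarizes "outperforms the null across the FPR range". The
null-calibrated threshold t' maximizes the gap between the target's TPR
and the null-median TPR at the matched FPR, ties to the more stringent
threshold.

Defaults use 1,000 null motifs, which keeps a desk-scale run in seconds
to minutes; the pipeline's `full` profile raises this to the
40,000–100,000 range used for genome-scale analyses.

## Category enrichment and the length-matched control

Per term, a two-sided Fisher test of the (in-term × 5UI) table is reported
with the LOD (log10 odds ratio, Haldane-corrected when a cell is zero),
sorted by LOD. The multiplicity adjustment is a min-p label resampling:
5UI labels are permuted over transcripts (fixing the number of labeled
transcripts, hence preserving the dependence among overlapping terms), the
minimum raw p across terms is recorded per permutation, and
`p_adj = (1 + #{min p ≤ p_raw})/(1 + B)` with monotone step-down
enforcement. The add-one form keeps the estimate valid at finite B. With
null annotations the family-wise rate of any `p_adj < 0.05` stays at the
nominal level (checked at 200 simulated datasets).

Because 5UIs are more common in genes with long 5'UTRs, an association
between a leader class and 5UI absence could in principle be a length
artifact. The control stratifies transcripts into 5'UTR-length quantile
bins and runs the Cochran–Mantel–Haenszel common-OR test across strata,
dropping zero-margin strata with a warning; with a single stratum it
reduces to the plain 2x2 Fisher association. This stratified design is a
documented substitute for length-matching procedures whose details are not
published, not a claim of equivalence to any specific one.

## The synthetic-data generator

The generator's defaults are the study conditions the analysis targets:
2,594 5UI− and 938 5UI+ sequences of one leader class; an 18.2% relative
adenine depletion in the first 69 nt; L:I and R:K pooled odds-ratio
targets of 1.55 and 2.1; a planted `CGSSGC` consensus with presence
fractions 47.5% / 22.2%, multi-copy fractions 26.8% / 7.14%, and 1-based
median hit positions 39 / 45; and log-normal 5'UTR lengths with medians
126 / 225 nt (a 99-nt difference), the 5UI+ group carrying one 5'UTR
intron.

Design choices, each made once:

* **Codon model.** The leader window is the initiator ATG plus 22 codons
  drawn from a hydrophobic-rich amino-acid profile, uniform over
  synonymous codons, tilted by per-codon adenine and thymine weights
  (`p(c) ∝ profile(aa)/n_syn · wA^{#A} · wT^{#T}`). The adenine weight is
  solved per group so the expected A count hits its target; the target
  median is 11 A per 69 nt for the 5UI+ group (~15.9%, leader-like), and
  the 18.2% depletion equals 2/11 exactly, so both group medians are
  integers — on a fixed 69-nt window the observable medians move on a
  1/69 grid, and non-integer targets cannot be recovered to arbitrary
  precision.
* **Conditions are realized, not sampled.** The planted copy counts are an
  exact composition (round(n·fraction) sequences with 2 copies, etc.,
  randomly assigned), 5'UTR lengths are a random permutation of the
  log-normal's empirical quantiles, and the positive-group profile
  multipliers are solved so the post-tilt, post-planting pooled odds
  ratios equal their targets. A validation generator should realize its
  configured conditions rather than approximate them in expectation.
* **Planting interacts with composition.** The planted motif is A-free
  and GC-rich: overwriting background with it depletes adenine and
  creates arginine codons, more so in the more-planted 5UI− group. The
  adenine solve is corrected by the expected overwrite fraction, and the
  odds-ratio calibration uses the exact expected per-copy amino-acid
  delta (enumerated over phases, partial-codon overlaps and degenerate
  letter options).
* **Graded planted sites.** Degenerate S positions instantiate to C with
  probability 0.6 in the 5UI− group and 0.5 in the 5UI+ group. Functional
  occurrences sitting closer to an optimal instantiation than
  unconstrained ones is exactly the relaxed-selection picture; it also
  matters technically: with uniform instantiation every planted site
  scores identically under an S-symmetric PSSM, the ROC collapses to a
  single jump at FPR = 0.222, and TPR at smaller grid FPRs is
  structurally zero. The mild bias grades the site scores so the ROC has
  support across the whole 0.1–0.7 FPR range, as real graded occurrences
  do.
* **Exact truth ledger.** After planting, the background is scrubbed of
  chance consensus matches (one base of each spurious match, outside any
  planted window, is flipped to A/T, which cannot create a new match for
  an A/T-free consensus). Two copies in one sequence sit at least 2w−1
  apart so no window can straddle both without containing a scrubbable
  background base. Every planted instance is therefore recoverable by the
  scanner with 100% recall and no false entries, which is what makes
  binomial-CI recovery checks of the presence/multiplicity fractions
  meaningful.
* **Positions.** Planted positions follow 3 + negative binomial (size 20)
  truncated to the scan region; size 20 gives the concentrated, mildly
  right-skewed 5'-biased shape seen in positional histograms of this kind
  of motif. The mean is solved so the mid-distribution median of the full
  occurrence mixture — including the pair-separation constraint, whose
  rejection step would otherwise shift the marginal — sits exactly at the
  configured value.

What the generator does **not** emulate: genome-wide GC isochores,
length variation of real CDSs, 3'UTRs and full-length mRNAs, codon usage
coupled to expression level, the phylogenetic dependence among related
genes (the redundancy module is exercised on synthetic duplicates
instead), and any realistic correlation structure between leader features
beyond the ones explicitly planted. Passing recovery tests on this
generator therefore demonstrates that the pipeline measures what it
claims to measure under the stated statistical structure — not that the
biological effects exist; that evidence belongs to the genome data the
original analysis used.

## Numerical choices and degenerate inputs

* Hypergeometric sums and Fisher p-values run in log space with a
  max-shifted log-sum-exp; the pmf-ordering rule uses the customary
  `(1 + 1e-7)` relative tolerance.
* Exact Wilcoxon enumeration is used for pooled samples of at most 12
  without ties; the exact path refuses ties, and the tie-corrected,
  continuity-corrected normal approximation handles everything else.
* The one-sample KS comparison fits the normal's parameters from the data
  and reports the nominal p-value; with estimated parameters that p is
  conservative in the classical sense, which matches how goodness-of-fit
  panels of this kind are usually read.
* PSSM probabilities are floored at 1e-300 before taking logs, so an
  indicator column yields a very large negative score rather than NaN.
* Tie-breaks are deterministic everywhere: leftmost window in overlap
  collapse, larger (more stringent) threshold for t\* and t', and seeded
  uniform draws for all representative selections.
* Degenerate inputs return defined results instead of errors where a
  defined result exists: zero-margin tables give p = 1 with a missing
  odds ratio, empty hit sets give zero-count reports without test
  p-values, and constant vectors give a zero bootstrap SE.

## Problem sizes used in validation

The package's own validation uses desk-scale versions of the analysis,
chosen as the sizes at which every check is statistically meaningful:
exhaustive 2x2 enumeration to N = 50; 1,000 random scanner instances;
recovery of all planted effect sizes at 500 sequences per class; ranking
of the planted-site PSSM against 1,000 Dirichlet nulls over FPR 0.1–0.7;
family-wise error calibration over 200 simulated datasets of 50 null
terms at 500 resamples; and a null self-ranking calibration with a fixed
null ensemble of 200 motifs and 200 independent targets. The
`scripts/acceptance.R` report regenerates the dataset at the full default
set sizes (2,594 / 938) and recomputes the headline quantities end to end
from the written files.

## Known limitations

* The redundancy dialect (identity/overlap with word seeding) is not an
  E-value model; borderline homologies that blastn would link at
  E < 1e-25 but that share no exact 10-mer in the first 99 nt can be
  missed.
* Per-gene "mean ratio" summaries drop genes whose denominator amino acid
  is absent (the count is reported); no pseudocount variant is offered.
* The min-p adjustment assumes exchangeability of labels under the null
  (subset pivotality for FWER control), which label permutation provides
  here but which is not a universal property of resampling schemes.
* The stratified length control tests association within length strata;
  it does not model continuous confounding beyond the bin resolution
  (10 quantile bins by default).
* The exhaustive k-mer finder is limited to k ≤ 8 and the S/W degenerate
  alphabet; it is a plumbing-level stand-in, not a motif-discovery method.

## A minimal run

```{r example, eval = FALSE}
library(alrexscan)

cfg <- default_config(profile = "test", outdir = "alrex_run", seed = 1)
manifest <- run_pipeline(cfg)

# or stage by stage:
d <- gen_dataset(synthetic_config(n_pos = 500, n_neg = 500, seed = 1))
pssm <- pssm_from_sites(d$truth$instance,
                        background = sequence_background(d$records$cds))
hits <- scan_transcripts(pssm, d$records)
maxima <- tapply(hits$score, hits$transcript_id, max)
```
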