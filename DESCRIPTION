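Package: alrexscan
Title: Coding-Region Motif and Codon-Bias Analysis by 5'UTR Intron Status
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Relates the presence or absence of 5'UTR introns (5UIs) to
    nucleotide-level features at the 5' end of coding regions, the signature
    of the alternative mRNA export (ALREX) pathway in signal-sequence (SSCR)
    and mitochondrial-targeting (MSCR) coding regions. Provides annotation
    parsing and 5UI derivation from refGene-like tables, 69-nt leader-window
    codon composition statistics (adenine/thymine depletion, paired
    amino-acid preferences), PSSM motif scanning with overlap disambiguation
    and enrichment-optimal score thresholds, Dirichlet random-PSSM ROC null
    models with percentile ranking, resampling-corrected category enrichment
    with a 5'UTR-length-matched stratified control, and a calibrated
    synthetic-data generator that lets the whole pipeline run and be
    validated without genome-scale downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
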