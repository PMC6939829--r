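Package: asmqc
Title: Genome Assembly Comparison, Validation-Read Evaluation, and Haplotig Purging
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for choosing among competing de novo genome assemblies
    of heterozygous (typically diploid) organisms. Implements validation-read
    holdout splitting, read-set summaries, canonical k-mer histograms with
    haploid genome-size estimation, contig contiguity statistics (N50/L50, GC,
    assembly ploidy), an anchor-seeded chained aligner for contig-to-contig
    and whole-assembly similarity coverage, gene-conservation-informed contig
    alignment (GCICA) haplotig detection and purging, base-level error rates
    and split-read structural-variant counts from validation-read alignments,
    a synthetic diploid genome and read simulator with ground truth, and a
    ranked multi-metric comparison report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
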