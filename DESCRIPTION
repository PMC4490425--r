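Package: codonbias
Title: Codon Usage, Codon-Pair Context and Positional Bias Analysis for
    Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics of synonymous codon usage for corpora of validated
    open reading frames: codon counting, relative synonymous codon usage
    (RSCU), synonymous codon usage order (SCUO), GC partitioning by codon
    position, codon-pair counting at junction distances 0-5 with relative
    synonymous codon pair usage (RSCPU), preferred/avoided calling under the
    Audic-Claverie count test, position-dependent Kullback-Leibler divergence
    profiles against a synonymous-shuffle null, start/stop sequence-context
    information matrices, dinucleotide and trinucleotide relative abundance
    (CpG and CWG odds ratios), GC3 stratification, and cross-species
    comparison by RSCU clustering, principal components and codon-context
    adjusted-residual trees.  Includes a synthetic ORF-corpus generator with
    known codon, codon-pair, positional and flanking-motif structure, and the
    synonymous-codon (SSC) and full-codon (SC) shuffling null models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
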