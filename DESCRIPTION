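Package: dysgene
Title: Transposable-Element Copy Number and Hybrid-Dysgenesis Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Pipeline for inferring P-element and hobo transposon load from
    sequencing alignments and linking it to hybrid-dysgenesis phenotypes in
    Drosophila. Estimates transposable-element copy number per isofemale line
    from depth ratios, calls insertion sites from split short reads and
    spanning long reads, profiles internally deleted element copies, and fits
    the multinomial, Poisson, permutation and bootstrap models that relate
    paternal element copy number, maternal cytotype and temperature to ovary
    and ovariole phenotypes. A synthetic-data module simulates line genomes,
    reads with truth alignments, and diallel-cross phenotype tables so the
    whole chain is testable without external data or an aligner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    lmtest,
    jsonlite
Config/testthat/edition: 3
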