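Package: gibeltx
Title: Comparative Transcriptome Toolkit for Sexual Diploid and Unisexual
    Triploid Crucian Carp
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable pipeline for the comparative transcriptome analysis of a
    sexually reproducing diploid and a gynogenetic triploid fish population.
    Implements reciprocal-best-hit ortholog identification, codon alignment by
    protein back-threading, Nei-Gojobori (1986) Ks/Ka estimation with
    Jukes-Cantor correction, Ks-histogram peak detection and molecular-clock
    divergence dating; allele-multiplicity (di- versus tri-allelic)
    classification from read pileups; perfect-microsatellite detection and
    genotyping; hypergeometric functional-category enrichment; exact-test
    differential expression with Benjamini-Hochberg control and
    expression-pattern grouping; and 2^-ddCq relative quantification. A
    synthetic-data module generates every pipeline input with known ground
    truth: diverged ortholog pairs, triploid and diploid pileups from planted
    genotypes, microsatellite-bearing transcripts, and two-condition count
    tables with planted fold changes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
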