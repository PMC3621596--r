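Package: evotol
Title: Genome-Scale Analysis of Solvent Tolerance in Yeast Deletion and
    Evolved Strains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for reverse-engineering n-butanol tolerance in
    Saccharomyces cerevisiae from genome-scale experiments: butanol
    sensitivity index (BSI) screening of gene-deletion collections from
    plate-reader growth curves, hypergeometric GO-term enrichment with
    annotation propagation and false-discovery-rate control, a
    quality/depth/parental-subtraction filter chain for resequencing
    variant calls, codon-level annotation of coding and promoter-proximal
    variants, and stochastic simulation of marker-assisted backcross
    segregation to quantify causal versus neutral allele retention.
    Includes calibrated synthetic-data generators (dose-dependent growth
    inhibition, variant tables, annotation tables, multi-locus haploid
    genotypes) so the whole pipeline runs on simulated inputs plus small
    packaged reference tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite,
    Biostrings,
    rtracklayer
Config/testthat/edition: 3
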