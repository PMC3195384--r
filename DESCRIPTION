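Package: pbrselect
Title: Codon-Partitioned Tests of Positive Selection at MHC Peptide-Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Molecular-evolution toolkit for detecting positive (balancing)
    selection on MHC class II DRB exon 2 alleles and similar coding
    alignments. Implements Nei-Gojobori (1986) counting of synonymous and
    nonsynonymous sites and differences with multiple-pathway averaging,
    Jukes-Cantor multiple-hit correction, Kimura 2-parameter nucleotide
    distances, codon-bootstrap standard errors, and the one-tailed Z-test of
    positive selection, all stratified by a peptide-binding-region codon
    mask. Also provides per-site amino-acid polymorphism tables, pairwise
    identity summaries, Poisson-corrected Neighbor-Joining phylogenies with
    bootstrap supports, a codon-substitution simulator for generating allele
    families under site-class-specific selection intensity, and a pipeline
    producing publication-style selection, polymorphism and tree reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    seqinr,
    stats,
    tools,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
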