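Package: ystrseq
Title: Sequence-Based Y-STR Allele Decomposition, Nomenclature and
    Phylogenetic Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing massively-parallel-sequencing data at the 23
    PowerPlex Y23 Y-chromosomal short tandem repeats. Parses full-length allele
    sequences into repeat-block decompositions against a packaged locus
    catalogue, produces capillary-electrophoresis-compatible allele names and
    full bracketed sequence designations (including uncounted-block naming
    rules for DYS19, DYS385a,b, DYS390 and DYS481), collapses reads into
    depth-thresholded stutter-aware allele calls, distinguishes constitutive
    allele duplications from somatic mutants by relative read-depth ratios,
    classifies sequence variants as monophyletic or polyphyletic on a sample
    phylogeny by Fitch parsimony, and summarises sequence-level diversity
    (isometric allele groups, novelty filtering). A seeded simulator generates
    phylogenetically structured synthetic panels (trees, slippage and SNP/indel
    mutation, read depths with stutter) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
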