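Package: slcid
Title: Genome-Wide Identification and Family Classification of Solute
    Carrier Transporters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies solute carrier (SLC) transporters in arthropod
    proteomes and sorts them into the 66 numbered SLC families. Candidate
    proteins are screened with family profile-HMM hits, assigned to
    families by reciprocal protein-BLAST criteria against a curated model
    species reference, and filtered on polypeptide length and
    transmembrane-domain counts derived from the curated families.
    Downstream tools compare family sizes across species: proteome
    completeness gating, per-family one-way ANOVA with Bonferroni
    correction and effect sizes, coefficients of variation, hierarchical
    clustering of species, and export of gene-family count files with a
    pruned ultrametric tree for birth-death family-evolution software.
    Includes seeded synthetic-fixture generators with known ground truth
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
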