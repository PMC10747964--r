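Package: lymphscan
Title: Mapping Lymphoma Risk Loci in Pure-Breed Dog Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case-control mapping of inherited cancer risk in
    closed dog-breed populations: pedigree kinship matrices, NetView-style
    mutual k-nearest-neighbour relationship networks, mixed-linear-model
    genome-wide association with Storey q-values (genome-wide and
    chromosome-wise), composite selection signals combining Fst, delta-DAF
    and XP-EHH, sliding-window haplotype and homozygosity analysis with
    Fisher exact contingency tests, and recessive-pattern filtering of
    sequence variants against gene annotation. Includes a pedigree
    gene-dropping simulator with a planted recessive risk haplotype and a
    multi-breed reference panel generator so the whole pipeline can be
    exercised and tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    igraph,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
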