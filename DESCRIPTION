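Package: wsdecipher
Title: Multi-Data Integration for Candidate Genes, Variants and
    Genotype-Phenotype Association in Waardenburg Syndrome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage analysis pipeline for deciphering molecularly
    undiagnosed Waardenburg syndrome (WS). Stage one prioritizes candidate
    disease genes by intersecting consensus protein-protein interaction
    partners of the seven known WS genes with genes ranked by phenotype
    similarity against the pooled WS phenotype set (weight W_g = N_g/N_ws).
    Stage two nominates candidate disease-causing variants through a
    five-predictor consensus deleteriousness filter (SIFT, PolyPhen2-HVAR,
    MutationTaster, CADD-phred, GERP++), cross-reference against known
    pathogenic variants, per-residue conservation against a cross-species
    protein alignment, and protein-domain localization. Stage three runs
    genotype-phenotype association analysis on a curated patient cohort
    with missing-aware prevalence, Pearson chi-square and exact tests, and
    phi-coefficient phenotype co-occurrence. A seeded synthetic-data module
    emulates every input with retained ground truth so the whole pipeline
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
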