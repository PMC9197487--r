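Package: stargazeR
Title: Multi-Evidence Drug Target Prioritization from PheWAS, GWAS,
    Druggability and Protein Interaction Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Integrates disease-target association evidence from
    PheWAS- and GWAS-style catalogs, gene-disease association scores,
    target development level (TDL) druggability annotations, and
    protein-protein interaction connectivity into five normalized
    per-gene feature scores and a single aggregate StarGazer score used
    to rank candidate drug repositioning targets per phenotype.
    Provides file-backed evidence providers, a deterministic
    synthetic-data generator with independent ground truth, eight
    exploration modes (gene, variant, PheWAS, GWAS, union,
    intersection, protein interaction network, prioritization) and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
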