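Package: missdriver
Title: Cancer-Type-Specific Classification of Driver and Passenger
    Missense Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Feature engineering and classification of somatic missense
    mutations into cancer drivers and passengers. Extracts sequence-based
    features (amino-acid property changes, AAindex substitution-matrix and
    contact-potential terms, physicochemical neighbourhood composition,
    gapped di-/tri-peptide motif odds ratios, PSSM profile features,
    conservation and disorder tracks), structure-based features from
    predicted models (pLDDT, solvent-accessible surface area, residue
    depth, secondary structure, inter-residue contacts) and amino-acid
    contact-network centralities. Provides mutation-preference statistics
    (substitution odds ratios, Wilson confidence intervals, Fisher exact
    composition tests), feature selection, a seeded feed-forward neural
    classifier trained with stochastic gradient descent, protein-grouped
    data splitting, stratified cross-validation, and a deterministic
    synthetic-fixture generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
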