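Package: tetrascreen
Title: Multiplexed Combinatorial Peptide-MHC Tetramer Screening by Mass
    Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design and deconvolution of triple-coded metal-barcoded
    peptide-MHC tetramer screens acquired by mass cytometry (CyTOF).
    Provides combinatorial barcode-scheme generation and validation,
    logicle transformation, palladium sample de-barcoding, hierarchical
    lineage gating to live CD8+ and CD4+ T cells, decoding of
    triple-tetramer-positive events into per-peptide detection records,
    objective hit calling (per-configuration event-count thresholds,
    CD8-versus-CD4 comparison, two-fold cross-configuration concordance,
    phenotypic-homogeneity and healthy-donor background audit metrics),
    phenotype profiling of antigen-specific hits (marker positivity,
    memory-subset classification, PCA plus k-means clustering, rank-based
    group comparison, t-SNE embedding), and the neoepitope candidate
    selection cascade (RNA-evidence filter, 8-11mer enumeration, IC50
    cutoff, optimal HLA-peptide pairing). A seeded synthetic
    mass-cytometry event generator emulates barcoded PBMC staining runs
    with planted antigen-specific populations so the whole pipeline is
    exercisable and testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
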