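Package: phoshx
Title: Phosphosite Hotspot Ranking, Differential Phosphoproteomics,
    HX-MS Residue Uptake, Enzyme Kinetics and Structural Superposition
Version: 0.1.0
Authors@R:
    person("phoshx", "developers", email = "phoshx@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for the quantitative analyses behind a
    phosphorylation hotspot study of the tyrosine phosphatase SHP2:
    phosphoproteome hotspot scoring from PhosphoSitePlus-style site
    tables, tumor-versus-wildtype differential phosphosite enrichment
    (Wilcoxon rank-sum with Benjamini-Hochberg control), pseudo-residue
    differential deuterium uptake maps from hydrogen-deuterium exchange
    mass spectrometry peptide centroids with back-exchange correction,
    Michaelis-Menten / IC50 / thermal-melt curve fitting, and rigid-body
    Kabsch superposition of protein structures. Seeded synthetic-data
    generators emulate every input format so all stages can be exercised
    and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
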