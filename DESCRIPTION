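Package: craniometrics
Title: Photogrammetric Cranial Measurements and Mean Shape Analysis
Version: 0.1.0
Authors@R:
    person("Craniometrics", "Developers", email = "craniometrics@example.org",
           role = c("aut", "cre"))
Description: Measurement framework for three-dimensional photogrammetric head
    scans of infants treated for sagittal synostosis. Registers triangle meshes
    to the anatomical reference frame defined by the nasion and both tragi,
    extracts orthogonal cranial slices, computes photocephalometric
    measurements (occipitofrontal diameter, biparietal diameter, head
    circumference, cephalic index, corrected intracranial volume), converts
    them to age- and sex-specific z-scores against growth-reference tables,
    builds pointwise mean cranial shapes with SD bands per group, and compares
    groups with an assumption-gated test-selection procedure (Shapiro-Wilk and
    Levene gate, one-way ANOVA or Kruskal-Wallis, pairwise t or Conover-Iman
    post hoc with Bonferroni correction). Includes a synthetic-head generator
    with analytic ground truth for offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
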