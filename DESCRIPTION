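Package: taxsetdist
Title: Distances Between Sets of Hierarchical Taxonomic Clinical Concepts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolbox for measuring semantic distance between hierarchical
    taxonomic clinical concepts (ICD-10-style diagnosis codes) and between
    sets of such concepts at the patient and subpopulation level. Implements
    path-based and ontology-based information content, four code-level
    distance formulas (binary, Wu-style information-theoretic, Li's
    parameterised form, and a simplified variant), and eight set-level
    distances including minimum weighted bipartite matching solved by the
    Hungarian algorithm. Builds ranked diagnosis prototypes for patient
    subpopulations, fits a nearest-prototype classifier for hospital
    length-of-stay, and generates synthetic taxonomies and cohorts with
    controlled subpopulation structure for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
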