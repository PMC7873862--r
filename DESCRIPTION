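Package: gsmforge
Title: Genome-Scale Metabolic Network Reconstruction, Curation, and
    Validation for Oleaginous Yeasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to assemble a draft genome-scale metabolic network for a
    target organism by transferring reactions from donor models through an
    ortholog map, to audit and curate the draft (duplicate detection, mass
    and charge balance, dead-end reporting), to build a biomass objective
    with a lean-biomass versus lipid-body split of fatty-acid composition
    estimated by segmented regression, to simulate growth by flux balance
    analysis with a built-in bounded-variable simplex solver (including
    gene deletions through gene-protein-reaction logic and mixed-integer
    detection of energy-generating cycles), and to score model predictions
    against growth-phenotype arrays and gene-fitness tables with
    confusion-matrix statistics.  Includes seed-deterministic synthetic
    data generators with known ground truth and a hand-curated demo
    network covering pentose and p-coumarate catabolism of an oleaginous
    yeast.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
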