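Package: trunkvoc
Title: Constitutive and Herbivore-Induced Trunk Volatile Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of longitudinal trunk volatile emissions
    measured by thermal-desorption GC-MS from enclosure sampling of tree
    trunks. Computes linear retention indices from an n-alkane ladder and
    annotates deconvoluted components against a reference library, converts
    component areas to bark-area- and time-normalized emission rates through
    calibration curves with surrogate-standard mapping, separates trunk
    volatiles from ambient background, classifies compounds into
    constitutive, herbivore-induced, neighbor-induced and stress-induced
    volatiles by detection-frequency and fold-change rules, models temporal
    emission dynamics with a four-parameter asymmetric peak function, groups
    emission time series by Kendall rank correlation, and compares emission
    rates with Kruskal-Wallis and Dunn tests. Ships a synthetic study
    generator that emulates a three-tree, three-phase infestation experiment
    so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
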