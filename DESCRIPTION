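Package: spnmeta
Title: Meta-Research Toolkit for Sustained Posterior Negativity Catalogues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for catalogue-scale evaluation of the sustained posterior
    negativity (SPN), an event-related potential elicited by visual symmetry.
    Provides a plain-text interchange format for condition-averaged ERP
    catalogues, a seeded synthetic catalogue generator, windowed electrode-
    cluster amplitude extraction with within-subject effect sizes, noncentral-t
    power analysis and sample-size solving, exact binomial sign-test
    thresholds, publication-bias diagnostics (random-effects meta-analysis,
    funnel asymmetry, cumulative amplitude distributions), electrode-cluster
    robustness ("vibration") analysis, and a spatio-temporal cluster-based
    permutation test over electrode-by-time grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    metafor,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
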