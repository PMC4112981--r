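Package: crossreact
Title: Structural Similarity Triage of Steroid Immunoassay Cross-Reactivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing and predicting cross-reactivity of steroid
    hormone immunoassays from two-dimensional molecular structure. Computes
    166-bit structural-key fingerprints and Tanimoto similarity between
    candidate compounds and the target hapten of an assay, derives percent
    cross-reactivity from spiked-sample measurements and bins it into the
    standard strong/weak/very-weak/none categories, estimates the apparent
    analyte concentration a cross-reactant produces at published plasma
    concentrations together with a clinical-likelihood grade, and evaluates
    similarity cutoffs as a triage classifier. Ships transcribed
    cross-reactivity panels for five clinical assays (cortisol, DHEA sulfate,
    estradiol, progesterone, testosterone) and a synthetic assay-panel
    simulator so the whole pipeline can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
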