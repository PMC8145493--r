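Package: acaritox
Title: Compatibility Scoring, Probit Dose-Response and Joint-Toxicity
    Analysis for Fungus-Toxin Acaricide Bioassays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating combinations of an entomopathogenic
    fungus with a plant secondary metabolite against arthropod pests.
    Implements the Biological Index for fungus-toxin compatibility
    (weighted combination of vegetative growth, conidiation and conidial
    germination relative to an untreated control), Abbott correction of
    control mortality, maximum-likelihood and least-squares probit
    concentration-mortality regression with LC50 point estimates and
    Fieller-type fiducial limits under heterogeneity inflation,
    proportional mixture designs, additivity-expected mixture LC50s with
    a joint-toxicity index and synergism/antagonism classification, and
    a seeded simulator for growth assays and quantal mortality bioassays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
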