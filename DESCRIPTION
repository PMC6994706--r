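Package: callosoplan
Title: Computer-Assisted Trajectory Planning for Laser Anterior Two-Thirds
    Corpus Callosotomy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Planning pipeline for minimally invasive laser interstitial
    thermal therapy (LITT) anterior two-thirds corpus callosotomy. Generates
    anterior, middle and posterior callosal target regions from a labelled
    whole-brain parcellation by morphological dilation and Boolean
    intersection; searches entry-gyrus/target pairs under length, drilling
    angle and ventricle constraints; scores candidate trajectories against a
    vessel segmentation with a 128-node vascular risk score, minimum vessel
    distance, intracerebral length, drilling angle and the proportion of the
    catheter within the corpus callosum; simulates pull-back laser ablation
    cavities; and quantifies residual interhemispheric connectivity by
    filtering streamlines through the simulated cavities. Ships a parametric
    digital head phantom (parcellation, vessel tree, interhemispheric
    streamlines) so the whole pipeline is exercisable without patient data,
    plus minimal NIfTI-1 and TCK readers/writers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
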