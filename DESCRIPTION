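Package: hemiconn
Title: Hemispheric Structural Connectivity Conservation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the conservation principle of structural
    brain connectivity: the inverse relationship between interhemispheric and
    intrahemispheric connectivity in diffusion-MRI connectomes. Generates
    synthetic multi-center cohorts of streamline-count/fiber-length
    connectomes with planted inter/intra coupling, site batch effects and
    disease effects; computes interhemispheric (commissural ratio, corpus
    callosum area ratio) and intrahemispheric (mean shortest path length,
    efficiency) measures on length-normalized, cortical-only connectivity
    graphs; harmonizes measures across acquisition centers with a parametric
    empirical-Bayes location/scale batch correction (ComBat); and runs the
    covariate-residualized correlation and three-group ANOVA/Tukey battery
    relating connectivity to structural and clinical variables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
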