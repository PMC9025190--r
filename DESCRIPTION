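Package: miomet
Title: Microbiome-Metabolome Association, Prediction and Mediation Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for joint gut-microbiome and urine-metabolome
    cohort data: probabilistic quotient normalisation of metabolite panels with
    restricted cubic splines and a 4-SD outlier rule, linear mixed-model screens
    of metabolites against genus abundance, genus presence and alpha diversity
    with Benjamini-Hochberg correction and bootstrap sensitivity p-values,
    microbiome-based metabolite prediction scores from an elastic-net objective
    solved by coordinate descent with cross-validated grid search, mediation
    analysis of diversity effects on health markers through those scores, and
    reaction-abundance annotation of communities against genome-scale
    reconstruction summaries. A synthetic-cohort generator with planted,
    recoverable ground truth drives all validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    jsonlite,
    sandwich,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    vegan,
    yaml,
    withr
Config/testthat/edition: 3
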