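Package: metabocut
Title: Metabolic Phenotype Clustering and Waist Circumference Cutpoint Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for selecting population-specific waist circumference
    cutoff points for abdominal obesity via metabolic phenotyping. Implements
    SPSS-style two-step cluster analysis (CF-tree preclustering followed by
    log-likelihood-distance agglomeration with automatic cluster-number
    selection), stratified phenotype assignment into six metabolic phenotypes
    including metabolically obese normal weight (MONW) and metabolically
    healthy obese (MHO), split-half centroid cross-validation with Cohen's
    kappa, and stepwise phenotype-exclusion ROC analysis with Youden,
    closest-to-(0,1) and positive likelihood ratio cutpoint indices and
    DeLong AUC comparisons. Includes a synthetic cohort generator
    parameterised from published summary statistics of the Maracaibo City
    Metabolic Syndrome Prevalence Study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
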