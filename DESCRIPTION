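Package: benthoscape
Title: Benthic Habitat Mapping from Multibeam Bathymetry, Backscatter
    Mosaic and Angular Response
Version: 0.1.0
Authors@R:
    person("Benthoscape", "Developers", email = "benthoscape@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for supervised benthic habitat
    classification from multibeam echosounder surveys. Builds an
    angular-dependence-compensated backscatter mosaic from calibrated
    per-beam intensity samples, segments it into homogeneous regions by
    region growing, compiles one mean angular-response curve per segment
    and extracts statistical features (mean, least-squares slope, skewness,
    kurtosis over 30-50 degree incidence angles), derives standard terrain
    layers from bathymetry (slope, aspect, rugosity, curvature, bathymetric
    position index, complexity) and texture/colour-composite layers from
    the mosaic (GLCM homogeneity, entropy, correlation; HSI red/green/blue),
    and classifies the co-registered layer stack with a random forest,
    including importance-driven incremental feature selection and
    error-matrix accuracy assessment (overall accuracy, Kappa with
    large-sample variance, pairwise Z tests). A synthetic-survey module
    generates bathymetry, habitat maps, per-beam samples with class-specific
    angular response and ground-truth transects so the whole pipeline is
    testable without field data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
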