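Package: coloqc
Title: Objective Colonoscopy Quality Assessment from Pixel Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for objective quality assessment of
    colonoscopy recordings. Pixels of withdrawal-phase frames are classified
    into intestinal mucosa, residues, artifacts and lumen, first with a
    CIELAB colour-occupancy-cube classifier built from small patch
    libraries, then with a compact encoder-decoder semantic segmentation
    network trained on the automatically annotated frames. Per-frame pixel
    percentages are filtered by an artifact-validity rule, aggregated per
    colon segment, and converted into a 1-3 quality score comparable to the
    Boston Bowel Preparation Scale (BBPS); tie-corrected Spearman
    correlation and Cohen's kappa quantify agreement with expert BBPS
    scores. A synthetic frame generator with ground-truth masks makes the
    whole pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    farver,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
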