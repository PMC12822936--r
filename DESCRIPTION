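Package: dfuscore
Title: Scoring and Prognostic Validation of Diabetic Foot Ulcer
    Classification Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements four diabetic foot ulcer classification systems
    (Meggitt-Wagner, University of Texas, SINBAD, Saint Elian) and the
    statistical machinery used to externally validate them against a
    six-month major-amputation outcome: band-collapsed contingency tables
    with robust-variance relative risks, tie-aware ROC curves with DeLong
    variance and paired AUC comparisons, threshold sweeps with exact
    binomial confidence intervals and Youden-index cut-off selection,
    care-setting stratified discrimination, a paired-AUC power simulation,
    and a latent-severity synthetic cohort generator for end-to-end
    pipeline testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0), pROC, sandwich, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
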