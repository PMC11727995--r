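Package: woundscreen
Title: Automated Surgical Wound Infection Screening from Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-based screening of surgical-site infection from
    smartphone photographs of stapled abdominal wounds. Locates surgical
    staples with fuzzy gray-scale mathematical morphology, reconstructs the
    image under the staple mask by diffusion inpainting, quantifies
    peri-incisional erythema as the proportion of near-red pixels in HSV
    space, fuses the image call with a seven-item symptom questionnaire into
    a sensitivity-first triage decision, and provides the diagnostic
    accuracy statistics used to evaluate such a screen (sensitivity and
    specificity with exact confidence intervals, Cohen's kappa, ROC curves
    with Youden cutoff selection). A deterministic synthetic wound-photo
    generator with ground truth makes the whole pipeline testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    yaml,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
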