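Package: aceval
Title: Clinical Evaluation of PET Attenuation-Correction Methods on Digital Head Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the patient-by-patient clinical evaluation of
    attenuation-correction (AC) methods for amino-acid brain PET/MRI.
    Implements tumor delineation by tumor-to-brain-ratio isocontouring,
    attenuation-map class agreement (Dice, MAE, SSIM), PET agreement metrics
    (Dice, Hausdorff distance, shape deviation, peak-location distance, PSNR),
    clinical acceptance criteria on TBR and biological tumor volume,
    longitudinal change concordance, dynamic time-activity-curve comparison,
    and Bland-Altman agreement statistics on the log scale with a
    repeated-measures correction.  A synthetic digital head-phantom generator
    with injectable attenuation-map artifacts and a first-order
    attenuation-bias model allows the whole protocol to be exercised
    end-to-end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
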