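Package: paskin
Title: Photoacoustic and Ultrasound Analysis of Implant-Overlying Skin Vasculature
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Longitudinal analysis of combined ultrasound/photoacoustic (US/PA)
    imaging of the skin overlying subcutaneous implants. Provides 3-D skin
    segmentation from ultrasound, linear spectral unmixing of oxy- and
    deoxyhemoglobin from multiwavelength photoacoustic volumes, Hessian-based
    vessel enhancement (Jerman filter with Frangi-derived orientation and
    suppression of vertical implant-surface artifacts), three photoacoustic
    vascular biomarkers with baseline normalization, mixed-model and
    cross-correlation lag statistics against ordinal skin-health scores, and
    spatial hemoglobin-reduction mapping. Ships a synthetic phantom and cohort
    generator with ground truth so the whole pipeline is testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
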