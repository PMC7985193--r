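Package: lvecho
Title: Semi-Automated Murine Left-Ventricle Echocardiogram Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated analysis of murine left-ventricle ultrasound
    images. Segments parasternal long-axis B-mode frames by multi-atlas label
    fusion with normalized-mutual-information affine registration, traces the
    four short-axis M-mode wall interfaces with seed-bounded dynamic
    programming and spectral filtering, and derives the standard structural
    and functional endpoints (areas, method-of-disks volumes, ejection
    fraction, fractional shortening, stroke volume, cardiac output, LV mass).
    Includes a speckle-noise phantom simulator with exact ground truth, the
    validation statistics used to qualify such tools (Dice overlap,
    leave-n-out experiments, Pearson r-squared, triplicate coefficients of
    variation, paired t-tests), and a batch study workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
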