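Package: plaquekit
Title: Quantification of Disclosing-Gel Stained Dental Plaque in Oral Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying dental plaque in RGB oral photographs
    captured after application of a three-tone disclosing gel. Provides
    HSV-based preprocessing (lip suppression, brightness capping, white
    tooth suppression and color normalization to a canonical palette),
    three-class plaque segmentation (new, mature, over-mature), detector
    output evaluation (IoU matching, precision, recall, PR curves and
    mAP at IoU 0.5 from YOLO-format annotation files), and plaque burden
    scoring via the O'Leary index over four surfaces per tooth with
    Mild/Moderate/Severe categorization. A seeded synthetic stained-mouth
    generator produces ground-truthed images, labels, surface charts and
    true indices so the full pipeline can be exercised without clinical
    data; MixUp and CutMix augmentations are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    yaml,
    jsonlite,
    rlang,
    stats,
    grDevices,
    utils,
    tools
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
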