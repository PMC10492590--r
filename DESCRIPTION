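Package: mash
Title: Harmonize Hip-Accelerometer Activity and Wrist-Actigraph Sleep Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fuses concurrently worn hip-accelerometer (waking activity) and
    wrist-actigraph (sleep) minute-epoch data into coherent night-day-night
    24-hour sleep-wake compositions. Implements a two-tier harmonization:
    scored sleep bounds the waking interval when valid scored sleep surrounds a
    day; otherwise one-dimensional convolutional neural network epoch
    classifiers (dual-device or hip-only) predict the waking interval, with a
    bounded bivariate kernel-density correction for the tendency to confuse
    evening hip-device removal with sleep onset. Includes Choi non-wear
    detection, Evenson vector-magnitude intensity classification, an
    Actiware-style sleep scorer, a synthetic dual-device cohort generator with
    ground truth, and ROC/precision-recall and pre/post-correction evaluation
    tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
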