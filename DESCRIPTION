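Package: cardiowave
Title: Drug-Exposure Classification from Voltage-Sensitive Dye Line-Scan
    Recordings of Beating Cardiomyocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for voltage-sensitive dye (VSD) line-scan
    kymographs of spontaneously beating cardiomyocytes. Tracks cell
    membranes across line scans by Gaussian fitting, corrects
    photobleaching with a double-exponential model, extracts per-beat
    action-potential waveform metrics (maximum height, upslope, downslope,
    width at half-maximum, plateau height), and classifies the
    chronotropic drug exposure (control, propranolol, isoproterenol) of
    each waveform with a bagged decision-tree ensemble, including
    out-of-bag error curves, standardized permutation feature importance,
    sequential model reduction, and recording-level vote aggregation.
    Ships a calibrated synthetic-data generator that emulates the
    statistical structure of such recordings for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    randomForest,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
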