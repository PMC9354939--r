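Package: grainscan
Title: Line-Scan Grain Image Analysis and Threshed-Panicle Compensation for
    Rice Yield Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating rice yield-related traits from conveyor
    line-scan imagery: synthetic scene generation with exact ground truth,
    frame stitching, fixed-threshold grain segmentation with ellipse-based
    separation of isolated and touching spikelets, area-ratio spikelet
    counting, grain length/width measurement, threshed-panicle compensation
    of spikelet totals, object-detection building blocks (anchor generation,
    IoU, RoIAlign, squeeze-and-excitation gating, non-maximum suppression),
    and detection/agreement metrics (precision, recall, F1, average
    precision, R-squared, MAPE, RMSE). Includes a command-line interface
    for running the pipeline on PNG frame sequences with PASCAL VOC
    annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    EBImage,
    png,
    xml2,
    jsonlite,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
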