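Package: ctcnoise
Title: Interobserver Variability and Label Noise in Circulating Tumor
    Cell Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify interobserver variability in binary image
    annotation of circulating tumor cell (CTC) cutouts, construct
    consensus annotations by a binomial threshold, preprocess fluorescence
    image cutouts into hue/saturation feature vectors, and measure the
    effect of annotation noise on random forest and support vector machine
    classifiers under controlled cross-validation protocols. Includes a
    synthetic-data module that generates stylized three-channel cutouts
    and simulated observer panels with calibrated agreement structure, so
    the full analysis is reproducible without access to the original
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    withr,
    ranger,
    kernlab,
    EBImage,
    png
Suggests:
    tiff,
    jsonlite,
    ggplot2,
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
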