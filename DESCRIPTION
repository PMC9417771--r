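Package: toothseg
Title: Attention-Augmented U-Net Segmentation of Tooth CT Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semantic segmentation toolkit for 2D dental CT slices built
    around a U-Net encoder-decoder with dilated convolutions (output
    stride 16), atrous spatial pyramid pooling, and a channel-attention
    mechanism that replaces global average pooling by sub-region average
    pooling (SAP) and fuses low-level and high-level attention through a
    channel-expansion (CE) branch. Includes the matching preprocessing
    and augmentation pipeline (histogram equalization, CLAHE,
    normalization, random crop/flip/gray/shape perturbation), mean pixel
    accuracy and mean intersection-over-union evaluation, an SGD trainer
    with polynomial learning-rate decay, and a synthetic tooth-phantom
    generator that emulates the low-contrast, blurred-boundary statistics
    of dental CT so the whole system can be trained and tested without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
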