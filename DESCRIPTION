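Package: retivote
Title: Retinal Vessel Segmentation by Gray-Voting and Gaussian Mixture Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments both main and peripheral (small) vessels in retinal fundus
    photographs. The main vessel structure is extracted with an orientation-maximum
    2D Gabor wavelet filter bank; small vessels are enhanced with a local gray-voting
    operator; the two enhancements are fused multiplicatively and the fused intensities
    are clustered with a K-means-initialised Gaussian mixture model fitted by EM.
    Broken small-vessel fragments are then recovered from a second, more permissive
    gray-voting pass and grafted onto the mixture-model vessel mask, and residual
    non-vessel blobs are removed by a squareness-rate shape filter. Includes a
    synthetic fundus phantom generator with ground-truth vessel masks, pixel-level
    evaluation (sensitivity, specificity, accuracy) against one or two gold standards,
    and disagreement overlays.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
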