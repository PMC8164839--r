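Package: cshin
Title: Cell Shape Index Morphometrics, Tankyrase-Binding-Motif Scanning
    and Mask-Based Colocalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies cell morphology with the Cell Shape Index
    (CShin = Roundness/Circularity) computed on exact polygon geometry of
    cell outlines, compares CShin populations with the nonparametric
    battery used in junction-biology work (Mann-Whitney, Kruskal-Wallis
    with Conover-Iman post hoc and Benjamini-Hochberg adjustment), scans
    protein sequences for canonical and non-canonical tankyrase-binding
    motifs and reports their conservation across a precomputed multiple
    alignment, and measures two-channel fluorescence colocalization with
    threshold masks, mask products, count-based Manders M1/M2, Pearson
    correlation and Li's intensity-correlation analysis with ++PDM maps.
    A synthetic-data module generates wavy-bordered cell outlines and
    two-channel belt images with known ground-truth co-occurrence so the
    whole pipeline runs at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    EBImage,
    ggplot2,
    grDevices,
    mgcv,
    png,
    stats,
    tiff,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
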