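Package: lobdetect
Title: Sliding-Window Detection of Lobulation Imaging Signs in Lung CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A sliding-window framework for detecting the lobulation imaging
    sign (undulating margin indentations of round or oval lesions) in 2D lung
    CT slices. Provides Hounsfield-unit preprocessing and circular parenchyma
    masking, a 72-member template bank matched by FFT-accelerated normalized
    cross-correlation, local shape descriptors (dense SIFT, HOG, shape
    context, global curvature context, LIOP, LBP) pooled by bag-of-features,
    VLAD or Fisher-vector encodings and classified with a polynomial-kernel
    SVM, a Fourier-curvature bending-energy filter for false-positive
    reduction, detection metrics (APPI, SNTP, recall, precision, F1), and a
    synthetic lung-phantom generator with analytically known contours for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    e1071,
    mclust,
    jsonlite,
    png,
    tiff,
    yaml,
    withr,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
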