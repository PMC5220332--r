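Package: dynomics
Title: Delay Estimation and Co-Expression Screening for Time-Course Omics Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects, quantifies and corrects delays between time-course
    expression trajectories (for example miRNA versus mRNA, or orthologous
    genes across organisms). Each trajectory is decomposed with the discrete
    Fourier transform; the phase-angle difference at the reference's dominant
    frequency yields an initial integer delay estimate, which is refined by
    maximising the lagged Pearson correlation over a small set of candidate
    lags. Delayed positively or negatively correlated pairs are then screened
    at genome scale with correlation thresholds and Benjamini-Hochberg false
    discovery rate control. Includes a smoothing-spline resampler for raw
    unequally spaced time courses, a linear detrending helper, and a
    simulation benchmark comparing delay-aware association calling against
    plain and lagged Pearson correlation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
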