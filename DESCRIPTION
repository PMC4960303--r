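Package: isfcr
Title: Inter-Subject Functional Correlation Analysis of Multi-Subject Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for isolating stimulus-locked inter-regional correlation
    structure from multi-subject region-by-time BOLD-like recordings using
    inter-subject functional correlation (ISFC): the correlation between one
    region's time course in one subject and every region's time course in the
    average of all other subjects. Because intrinsic fluctuations and
    non-neuronal noise are uncorrelated across subjects, ISFC filters them out,
    whereas within-subject functional connectivity (FC) mixes all three signal
    components. The package provides group ISFC/FC/ISC estimation with Fisher
    r-to-z averaging, phase-randomization surrogate nulls with max-statistic
    family-wise error thresholds, permutation p-values, sliding-window
    connectivity fingerprints and their split-half reliability, segment
    reordering for history-dependence analyses, behaviour coupling with local
    regression smoothing, condition and interval decoding via nearest-template
    classification, k-means network discovery validated by Sorensen-Dice
    reproducibility, neighbourhood-correlation declustering, and a synthetic
    generator for the three-component (stimulus / intrinsic / noise) signal
    model used to validate every analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
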