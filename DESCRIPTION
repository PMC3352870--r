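Package: onhquant
Title: Optic Nerve Head Volumetry from 3D Spectral-Domain OCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic quantification of optic nerve head (ONH) volume
    and maximum height from 3D spectral-domain OCT volume scans, for grading
    papilledema. B-scans are denoised, the inner limiting membrane (ILM) is
    detected, retinal pigment epithelium (RPE) candidate pixels are selected
    and a least-squares spline is fit through the ONH to provide a reference
    surface; each B-scan is flattened on that surface and the edema area above
    a thresholded peripheral reference height is integrated into a volume
    (ONHV, mm^3) and a maximum height (ONHH, mm). Includes a synthetic OCT
    phantom generator with analytic ground truth, reliability and
    discrimination statistics (two-way mixed-effects intraclass correlation,
    rank-based ROC AUC, normative percentile cutoffs), readers and writers for
    TIFF-stack and raw volume formats, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    splines,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
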