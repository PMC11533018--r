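Package: dgmiron
Title: Deep Gray Matter Iron Quantification from QSM and R2* at 7T
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for brain iron quantification
    with ultra-high-field multi-echo gradient-echo (MGRE) MRI. Generates a
    digital susceptibility/R2* phantom and its complex MGRE signal, reconstructs
    quantitative susceptibility maps (Laplacian phase unwrapping, weighted field
    fitting, V-SHARP background-field removal, thresholded k-space division) and
    voxelwise R2* maps, extracts trimmed deep-gray-matter ROI statistics, and
    provides a cohort simulator plus the statistical layer (least-squares age
    regressions, Mann-Whitney group comparisons with Bonferroni correction)
    used to characterize iron deposition in normal aging.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    RNifti,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
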