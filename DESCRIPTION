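Package: loresd
Title: Local Response Function Estimation in Spherical Deconvolution for Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint voxel-wise estimation of a data-driven diffusion-MRI response
    function and fibre orientation distribution function (ODF) by constrained
    spherical deconvolution. The local response function is represented as a
    mixture of axially symmetric Gaussian kernels on a triangular grid of axial
    and radial diffusivities, and is estimated together with a unit-normalised
    ODF by sequential least-squares programming with an analytic gradient.
    Includes microstructural contrast maps (intra-axonal, extra-axonal, free
    water, response-function anisotropy), ODF modulation for tractography, a
    fixed-response multi-shell multi-tissue CSD baseline, and a voxel-level
    simulation harness with Rician noise and angular correlation coefficient
    validation. Reads and writes NIfTI images with FSL or MRtrix-style
    gradient tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    nloptr,
    quadprog,
    pracma,
    RNifti,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
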