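Package: coilsketch
Title: Coil-Sketched Reconstruction for Respiratory-Resolved Non-Cartesian Lung MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Memory-efficient iterative reconstruction of respiratory-resolved
    (4D) non-Cartesian lung MRI. Implements a non-uniform FFT encoding model with
    coil sensitivities and k-space preconditioning, Toeplitz embedding of the
    normal operator, SVD coil compression, randomized coil sketching of the
    data-consistency gradient with an intermittent full-operator anchor,
    total-variation / low-rank / motion-compensated low-rank regularizers with a
    forward-only proximal update, CG / FISTA / PDHG solvers, respiratory phase
    binning from a navigator signal, a seeded dynamic lung phantom and
    acquisition simulator, and evaluation utilities (masked NRMSE, convergence
    curves, pseudo-replica SNR).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: HDF5 (libhdf5)
Imports:
    Matrix,
    RNifti,
    yaml,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
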