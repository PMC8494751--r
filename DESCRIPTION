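Package: msotr
Title: Reconstruction and Multispectral Analysis of Optoacoustic Tomography Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Config-driven processing of multispectral optoacoustic tomography
    (photoacoustic) data: analytical paraboloid phantom simulation, sparse
    forward-model construction under curve-sampling (dIMMI) and exact
    arc-length (CDMMI) discretizations, image reconstruction by LSQR,
    non-negative accelerated projected gradient, or universal backprojection,
    per-frame signal preconditioning, sliding-window and Kalata alpha/alpha-beta
    multispectral state filters, linear spectral unmixing of oxy- and
    deoxy-hemoglobin with oxygen-saturation maps, and a metric/statistics
    suite for end-to-end validation on synthetic data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    parallel,
    yaml,
    jsonlite,
    minpack.lm,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
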