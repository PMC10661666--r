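Package: hpMRSI
Title: Simulation and Quantification of Parallel Hyperpolarized 13C
    Chemical-Shift-Imaging Experiments in Microfluidic Multiwell Devices
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward modelling and analysis of dissolution-DNP (dynamic
    nuclear polarization) chemical shift imaging (CSI) experiments in which
    a single hyperpolarized [1-13C]pyruvate dissolution is split across the
    eight wells of a microfluidic device and imaged repeatedly on an 8x8
    voxel grid. Provides the fluidic volume-distribution model with
    dead-volume calibration, a synthetic-data generator coupling
    first-order reaction kinetics (pyruvate decarboxylation by hydrogen
    peroxide) to hyperpolarized longitudinal-magnetization dynamics under
    repeated RF sampling, voxel-wise spectral synthesis with Lorentzian
    lineshapes and complex noise, CSI reconstruction and per-chamber voxel
    aggregation, peak quantification with SNR estimation, mono-exponential
    decay fitting, polarization-corrected concentration recovery, and
    time-normalized mass sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    minpack.lm,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'acquisition.R'
    'layout.R'
    'volume.R'
    'species.R'
    'kinetics.R'
    'signal.R'
    'csidata.R'
    'recon.R'
    'quantify.R'
    'io.R'
    'pipeline.R'
    'hpMRSI-package.R'
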