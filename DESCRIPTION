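Package: xemrsi
Title: Dissolved-Phase Hyperpolarized 129Xe MR Spectroscopic Imaging Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of dissolved-phase hyperpolarized 129Xe
    magnetic resonance spectroscopic imaging (MRSI) of the lung. Provides a
    synthetic lung phantom and simulated 3D Cartesian spherical-sampled MRSI
    acquisition, zero-filled Fourier reconstruction with point-spread-function
    tools, prior-knowledge constrained time-domain (AMARES-style) spectral
    fitting of the gas, membrane and red-blood-cell xenon resonances with
    Cramer-Rao lower bounds, quantitative gas-exchange maps (compartment
    ratios, chemical shifts, linewidths), regression models linking the RBC
    resonance to arterial oxygen partial pressure with voxel-wise paO2
    prediction maps, ventilation defect percentage, and lobe-wise regional
    statistics for the porcine lung.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, minpack.lm, jsonlite, RNifti
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'acquisition.R'
    'trajectory.R'
    'recon.R'
    'prior.R'
    'fit.R'
    'crlb.R'
    'oxygen.R'
    'snr.R'
    'maps.R'
    'regional.R'
    'io.R'
    'phantom.R'
    'simulate.R'
    'pipeline.R'
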