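Package: ufcosy
Title: Simulation and Reconstruction of Interleaved Ultrafast 2D COSY with
    Multi-Band Solvent Suppression
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward-models the acquisition of interleaved ultrafast
    (single-scan spatially encoded) 2D COSY spectra with an echo-planar
    spectroscopic imaging (EPSI) readout, as used for high-throughput
    screening of complex mixtures such as wine.  Includes a first-order
    spin-system peak-list simulator with a wine-like fixture, a pulse-sequence
    parameter model with derived acquisition geometry, frequency-selective
    multi-band solvent suppression presets (none, presaturation, multi-band,
    WET) with a receiver-gain plus two-component noise model, a raw-data
    simulator with per-transient amplitude/phase jitter, the standard
    processing chain (even/odd lobe splitting, interleave merging, spatial
    Gaussian apodisation, sine window, zero-filling, two-point chemical-shift
    calibration), and evaluation metrics (row-extracted SNR, 2D peak volumes,
    coefficient of variation across replicates, interleaving ghost prediction
    and detectability counts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
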