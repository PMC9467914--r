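Package: idpcstem
Title: Simulation, Reconstruction and Analysis for iDPC-STEM Cryo-Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrated differential phase contrast scanning
    transmission electron microscopy (iDPC-STEM) of frozen-hydrated
    specimens. Plans acquisitions from beam and dose physics (wavelength,
    convergence semi-angle, depth of focus, Nyquist pixel size, dwell and
    frame times), generates synthetic specimen potentials (helical rods in
    vitreous ice, gold resolution standards, atom clusters), simulates the
    scanning probe through a specimen by the multislice method with a
    segmented four-quadrant detector and Poisson shot noise, reconstructs
    iDPC images by Fourier integration of the differential phase contrast
    vector field, computes the contrast transfer function of the full
    imaging chain, and analyses micrographs (power spectra, helical layer
    lines, pixel-size calibration, Guinier and particle-number B factors,
    Fourier shell correlation). Reads and writes MRC2014 images and volumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
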