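Package: nmrlcm
Title: Linear Combination Modelling for Solid-State NMR Mixture Deconvolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Automated deconvolution of solid-state NMR (ssNMR) mixture
    spectra by linear combination modelling of two experimental template
    spectra (an amorphous and a crystalline solid-state form). The mixing
    proportion, zero- and first-order phase corrections, and horizontal
    chemical-shift alignments are estimated jointly by bound-constrained
    derivative-free optimisation of an L2 (residual sum of squares) or L1
    loss on the frequency-domain residuals. Includes JCAMP-DX and CSV
    spectral input/output, a synthetic complex-lineshape spectrum simulator
    with magic-angle-spinning sidebands for testing and validation, a
    session audit log for reproducible analyses, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
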