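Package: mmfscope
Title: Multimode-Fiber Needle Microendoscopy Simulation and Tissue Texture Discrimination
Version: 0.1.0
Authors@R: person("mmfscope", "developers", role = c("aut", "cre"),
    email = "mmfscope@example.org")
Description: Desk-scale simulation of transmission-matrix imaging through a
    multimode-fiber biopsy needle, together with the downstream analysis that
    discriminates tumor from normal tissue along a puncture path. Provides
    random transmission matrices, phase-conjugate focusing, binary Lee
    hologram encoding, off-axis interferometric calibration, angular-spectrum
    propagation, point-scan image formation with Brenner-function autofocus,
    synthetic tissue phantoms (alveolar and tumor textures, resolution
    targets), six spatial/spectral texture metrics, assumption-driven group
    statistics with Benjamini-Hochberg FDR and Cliff's delta, and dual-view
    (intensity + edge) PCA/K-means discrimination.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
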