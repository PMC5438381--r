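Package: eixpci
Title: Asymmetric Edge-Illumination X-Ray Phase-Contrast Imaging:
    Simulation and Multimodal Retrieval
Version: 0.1.0
Authors@R:
    person("eixpci", "developers", email = "eixpci@example.org",
           role = c("aut", "cre"))
Description: Forward simulation and closed-form retrieval for scanning
    asymmetric edge-illumination (EI) x-ray phase-contrast imaging. Models
    the bell-shaped illumination curve (IC) of a two-mask EI system, places
    the four asymmetric sampling points used by a single-object-scan
    acquisition, simulates Poisson-noisy per-column frame stacks from
    synthetic phantoms (transmission, refraction angle, scattering
    variance), and inverts them with the four-point second-order Taylor
    retrieval into co-registered absorption, differential phase contrast
    (DPC) and dark-field (DF) images. A single-image phase-map mode for
    quasi-homogeneous objects is included, together with a command-line
    pipeline (phantom, simulate, retrieve, demo) driven by a JSON
    configuration file.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
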