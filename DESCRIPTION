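Package: kaedeFlux
Title: Quantification of Photoconvertible Kaede Timelapse Assays of Axonal
    Local Translation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying local protein synthesis in growing axons
    from photoconvertible (Kaede) fluorescence timelapse imaging. The package
    converts two-channel z-stack timelapses into green/red ratio SUM
    projections, samples the ratio along a retrograde growth-cone trace,
    bins the profile, and fits the two-level regression statistic (spatial
    gradient per timepoint, gradient rate per axon) used to compare axons
    carrying a 3'UTR localization element against controls. A
    reaction-diffusion-transport simulator generates ground-truthed synthetic
    cohorts for validation, and satellite tools provide 3-D blob-based
    apoptotic cell counting and a bipartite zipcode motif scanner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
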