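Package: cxplaque
Title: Quantification of Connexin Gap-Junction Plaques in Retinal Wholemounts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Spectral-imaging pipeline for quantifying astrocyte connexin
    (Cx26, Cx30, Cx43, Cx45) gap-junction plaques in retinal nerve-fibre-layer
    wholemounts. Simulates ground-truthed lambda stacks rendered through six
    overlapping fluorophore emission spectra, performs per-voxel linear
    spectral unmixing (non-negative least squares), segments punctate plaques
    by 3D intensity thresholding, classifies each plaque into one of the 15
    connexin combination classes and into parenchymal versus vascular
    astrocyte compartments, and converts field-of-view counts to per-retina
    densities, totals, percent changes with age, and one-way ANOVA group
    comparisons with Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    igraph,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
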