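Package: mechanopore
Title: Quantitative Analysis of Microfluidic Cell Mechanoporation Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for contactless viscoelastic cell
    mechanoporation experiments: principal-curvature profiles of compressed
    cells modelled as oblate spheroids, biexponential fluorescence-lifetime
    (FLIM) decay fitting for membrane-tension readout, localization and
    angular-concentration statistics of high-tension points on the cell
    periphery, actin-cortex ring morphometry, nanoparticle counting and
    delivery-efficiency quantification from confocal z-stacks, mean-squared
    displacement transport classification of tracked particles, and a
    finite-volume diffusion simulator of nanoparticle uptake through
    membrane pores. Ground-truth synthetic generators emulate every input
    modality so each stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
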