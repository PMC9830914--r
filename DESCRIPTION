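Package: popdcquant
Title: Quantification of POPDC Membrane-Trafficking Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compartmental immunofluorescence quantification for studies of
    POPDC (Popeye domain containing) protein membrane trafficking. Segments
    muscle fiber cross-sections from a membrane-marker channel and measures
    sarcolemma-ring versus cytoplasm intensities per fiber, quantifies
    plasma-membrane localization ratios of co-expressed reporters in single
    cells, quantifies bimolecular fluorescence complementation signals, and
    fits type-1 quantitative BRET saturation curves to infer protein complex
    stoichiometry. Includes the accompanying nonparametric statistics layer
    (control-median normalization, distribution-free median confidence
    intervals, Mann-Whitney, Kruskal-Wallis with Dunn's post hoc test, one-way
    ANOVA with Dunnett's test) and seeded synthetic-data generators with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    jsonlite,
    multcomp,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
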