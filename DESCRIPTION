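Package: cciNeuroimmune
Title: Disability Phenotyping and Neuro-Immune Quantification for Sciatic
    Nerve Constriction Injury Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying rats into post-injury disability
    phenotypes from resident-intruder social behaviour, and for
    quantifying phenotype-specific immune signatures after chronic
    constriction injury (CCI) of the sciatic nerve. Implements the
    dominance-reduction classification rule, von Frey withdrawal
    threshold summaries, immunofluorescence field quantification
    (automated cell counting, cells per mm2, Otsu percent
    immunoreactive area, S100 injury/proximal ratio, ATF3 nuclear
    fraction), electron-microscopy measurement aggregation, and the
    statistical layer: censoring-aware multiplex cytokine summaries,
    sample-size-weighted combined-CCI means, one- and two-way ANOVA
    with Bonferroni post hoc contrasts, linear regression, and
    Benjamini-Hochberg false discovery rate control by assay family. A
    seeded synthetic-cohort generator (behaviour trajectories,
    withdrawal series, censored cytokine panels, ground-truth
    microscope fields) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
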