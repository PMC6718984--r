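Package: cimquant
Title: Quantification of Cell Polarity, Infiltration and Subcellular Marker
    Localization in Glioma Invasion Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable, tested implementations of three bespoke image-derived
    quantification procedures used in glioma invasion studies: scratch-assay
    cell-polarity scoring from nucleus and Golgi centroids with a sector-null
    chi-squared test and its noncentral-chi-squared power analysis; in vivo
    infiltration analysis of two mixed cell populations by distance-binned
    enrichment around an injection site with a Pearson trend test, plus tumor
    composition time-courses; and partitioning of immunofluorescence marker
    signal into nuclear, perinuclear-band and cytoplasmic/membrane fractions.
    Includes seed-deterministic synthetic-data generators (scratch fields,
    brain-section point patterns, multichannel images, composition schedules)
    with known ground truth so that every stage is verifiable by parameter
    recovery, and thin helpers for delta-delta-Ct relative expression and
    densitometry normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
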