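Package: oxwave
Title: Open-Search PTM Post-Processing and Redox Oxidation-Wave Analysis for
    Isobaric Time-Course Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processing of open-search peptide-spectrum matches for
    unbiased post-translational modification (PTM) discovery in isobaric
    (TMT) time-course experiments: precursor delta-mass recalibration,
    delta-mass histogram peak modelling, target-decoy false discovery rate
    at global, local and peak scope, Unimod-style annotation, truncation
    and site-position checks, and curation of modified peptides.
    Differential-alkylation (iodoacetamide / methyl methanethiosulfonate)
    readout classifies cysteine sites as reduced or reversibly oxidized.
    Quantification follows a weighted spectrum-peptide-protein hierarchy
    producing standardized log2-ratio deviations at the peptide (Zp),
    protein (Zq) and functional-category (Zc) levels, with a two-pass
    treatment that anchors modified peptides to protein values estimated
    from unmodified peptides.  Time-course tools cluster modified peptides
    by Pearson-correlation distance, extract oxidation-wave clusters, and
    score PTM and protein enrichment with hypergeometric statistics.  A
    synthetic-data generator with known ground truth makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
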