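Package: nucorg
Title: Nuclear Organization Analysis: Zone Assays, Tiling ChIP Binding Calls,
    and Expression Overlaps in Budding Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of subnuclear gene positioning and
    chromatin-factor occupancy in budding yeast. Implements the three-zone
    perinuclear position assay (equal-area concentric zones, chi-squared
    inference against a uniform null, exact binomial pore-colocalization
    tests), per-locus binding calls from tiling ChIP-chip probe sets via an
    exact Wilcoxon signed-rank test with full sign-pattern enumeration,
    cluster/peak extraction, factor-coincidence and subtelomere statistics,
    replicate differential-expression analysis with fold and significance
    classification and set-overlap summaries, and seeded synthetic-data
    generators so every stage runs end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    GenomicRanges
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
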