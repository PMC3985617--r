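Package: dualmark
Title: Selection Statistics and Escape Diagnostics for Dual Selectable
    Marker Genome Engineering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative tools for engineering and evaluating dual
    selectable markers (such as tolC in Escherichia coli) in multiplex
    recombineering workflows. Provides a multi-cycle CoS-MAGE
    allele-conversion simulator with empirical and zero-inflated binomial
    per-cycle conversion models and inoculum bottlenecks; growth-curve
    selection statistics (Normalized Selective Advantage, Normalized
    Culture Time, growth delay) from OD600 time-to-threshold; plating
    based counter-selection escape-frequency estimation with exact
    binomial intervals, fold reductions, and a two-agent independence
    model; multi-clone escape-mutation diagnosis from variant calls
    (effect classification against gene models, ancestral-variant
    filtering, per-gene recurrence tallies, genome binning,
    coding-length-normalized enrichment, and a duplication-site selection
    heuristic); and synthetic-data generators that emulate the
    statistical structure of all required inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
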