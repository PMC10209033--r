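Package: aspmine
Title: Statistically Significant Allergen-Specific Pattern Mining in
    Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exhaustive enumeration of contiguous amino-acid patterns that
    distinguish allergenic from nonallergenic proteins. Pattern significance
    is assessed by two-tailed Fisher exact tests on per-pattern contingency
    tables, with family-wise error rate control by Westfall-Young permutation
    calibration accelerated by branch-and-bound pruning of the pattern prefix
    tree. Significant patterns are screened into allergen-specific patterns
    (ASPs) by category-aware rules, merged into maximal concatenated patterns
    (ConcASPs) by overlapped concatenation within allergenic proteins, and
    used as interpretable indicator features in a sparse linear support
    vector machine evaluated by leave-category-out cross-validation. Includes
    a synthetic dataset generator with planted motifs and known ground truth
    for calibration and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    e1071,
    jsonlite,
    Biostrings,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr,
    yaml
Config/testthat/edition: 3
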