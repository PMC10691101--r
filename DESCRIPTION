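Package: quartetlineage
Title: Quartet and Triplet Methods for Cell Lineage Trees from Noisy
    Single-Cell Mutation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying and applying quartet- and triplet-based
    phylogeny estimation to tumor single-cell mutation data under the
    infinite-sites model with an unbiased error and missingness channel
    (false positives alpha, false negatives beta, missingness gamma).
    Provides exact pattern, quartet and triplet probability calculators
    with an exhaustive error-enumeration oracle, anomaly detection for
    quartets and triplets, a seedable matrix simulator, mutation-split
    support counting, and Maximum Quartet/Triplet Support Supertree
    solvers (exhaustive, constrained, and nearest-neighbor-interchange
    search) together with a consistency-experiment harness scored by
    false-negative branch error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
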