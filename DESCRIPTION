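Package: codonopt
Title: Codon Usage and Codon Context Optimization for Synthetic Gene Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Back-translates proteins into coding sequences whose individual
    codon usage (ICU) and/or codon context (CC, adjacent codon-pair usage)
    match a reference distribution learned from a host organism's
    high-expression genes. Provides a non-iterative individual codon usage
    optimizer (ICO), an elitist genetic algorithm for codon context
    optimization (CCO), and a multi-objective optimizer (MOCO) based on
    nondominated sorting with a reduced-storage domination-count ranking.
    Includes Pearson chi-squared tests for codon and codon-pair usage bias,
    leave-one-out cross-validation with a percent-codon-match metric and
    tournament comparison of design methods, and a synthetic host generator
    with controllable codon bias and first-order codon-pair structure for
    fully reproducible benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
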