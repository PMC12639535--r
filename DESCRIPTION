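Package: orthoscreen
Title: Transcriptomic Signature-Reversal Screening and Drug-Combination
    Nomination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens libraries of drug-induced transcriptomic signatures
    (LINCS L1000-style replicate-averaged Z-scores) against a binarized
    reference differential-expression profile. Computes the Normalized
    Concordance Ratio (NCR) with a gene-label permutation null and
    Benjamini-Hochberg correction, collapses replicate signatures to
    compound-level calls with an unweighted KS-style enrichment score,
    nominates candidate drug combinations with an orthogonality score, and
    builds a functional drug network from the Jaccard similarity of
    orthogonality-enrichment profiles with greedy-modularity community
    detection and centrality metrics. Ships a synthetic-screen generator
    with planted ground truth so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
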