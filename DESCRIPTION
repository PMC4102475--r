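Package: evomotif
Title: Evolutionary Construction and Selection of Interpretable Motif
    Features for DNA Sequence Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage evolutionary framework for binary classification of
    fixed-length DNA sequence windows. A genetic-programming stage evolves
    interpretable feature trees built from IUPAC degenerate motifs combined
    with boolean, positional, regional, shift and correlational operators,
    scored by a class-occurrence filter fitness and archived in a hall of
    fame. A genetic-algorithm stage then selects a relevant, non-redundant
    feature subset by maximizing a correlation-based merit. Includes a
    naive Bayes classifier over the selected features, evaluation statistics
    (auROC, auPRC, stratified cross-validation, paired t-tests, information
    gain), a k-mer spectrum baseline featurizer, and a synthetic generator
    that plants degenerate motifs into background sequence for controlled
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    optparse
Config/testthat/edition: 3
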