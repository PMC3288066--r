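Package: paccmit
Title: MicroRNA Target Prediction with Accessibility and Conservation
    Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts microRNA targets by enumerating seed matches in
    3'UTR sequences, filtering candidate sites by RNA secondary-structure
    accessibility (RNAplfold unpaired-probability profiles) and/or
    cross-species conservation (multiple-alignment derived), and ranking
    miRNA-3'UTR interactions by a single-hypothesis binomial
    over-representation P value (P_SH).  Ships parsers and writers for
    FASTA, MAF, RNAplfold '_lunp' tables and prediction TSVs, a
    synthetic-fixture generator with planted sites of controlled
    accessibility and conservation, and a benchmark harness (precision,
    targets per miRNA, true positives before the k-th false positive,
    rank-binned expression fold changes, precision-sensitivity curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    optparse,
    stats,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
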