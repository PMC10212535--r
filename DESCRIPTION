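Package: kamq
Title: k-mer Abundance Indexing with Counting Approximate Membership Queries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Indexes k-mer abundances from counted k-mer tables (KMC dump
    style) in a single-hash counting Bloom filter by storing constituent
    s-mers (s = k - z) together with their s-abundance, and answers
    streaming sequence queries as the sliding minimum over the z + 1 s-mer
    responses of each k-mer.  This wrapping reduces the false positive
    rate of the underlying counting filter by roughly a power of z + 1
    without creating false negatives or underestimated abundances.  Ships
    an in-place linear-time fixed-window sliding minimum/maximum
    algorithm, abundance discretization (identity, floor-log2,
    floor-log10), canonical k-mer support, evaluation metrics (false
    positive rate, construction false positives, overestimation score),
    and a synthetic-data harness that emulates metagenomic index/query
    experiments without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
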