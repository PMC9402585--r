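Package: netmet
Title: Network-Propagated Mutation Profiles for Tumor Recurrence Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Turns tumor/normal whole-exome mutation calls into
    network-propagated "heating" profiles and predicts cancer recurrence
    risk from them. Variants are purity-adjusted and classified into
    germline and founding-clone mutations from variant allele frequencies,
    reduced to functionally mutated genes by merging annotator calls, and
    diffused over a recurrence-specific signaling network by random walk
    with restart. A modified Multiple Survival Screening procedure
    discovers 30-gene network operational gene (NOG) signatures separating
    recurred from non-recurred tumors; combinatory signature sets vote
    through shrunken-centroid classifiers to call low/high recurrence
    risk. Includes the 21-gene Oncotype DX recurrence score as a
    comparator and a fully synthetic data generator for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    survival,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
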