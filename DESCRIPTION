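Package: epitriclust
Title: Tri-Clustering of Promoter Epigenetic Signals Across Cancer Types
    and Marks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies gene sets whose promoter-level epigenetic signal is
    coherent across subsets of cancer types and subsets of epigenetic marks.
    ChIP-seq style signal tracks are binned, depth-normalised with an inverse
    hyperbolic sine transform and summarised over promoter windows; per-gene
    Pearson-correlation itemsets of cancer types feed a from-scratch FP-growth
    frequent-itemset miner, per-mark bi-clusters are formed by inverse gene-set
    mapping, and maximal tri-clusters (gene set x cancer-type set x mark set)
    are mined by iterative cross-mark intersection with anti-monotone pruning.
    Includes a planted-pattern simulator and Jaccard recovery scoring for
    benchmarking, threshold-sweep diagnostics, tidy()/glance() methods and
    ggplot2 autoplot() visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
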