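Package: OverlapCorrect
Title: Machine-Learning Overlap Correction for Overlap-Layout-Consensus
    Genome Assembly
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects candidate read overlaps for overlap-layout-consensus
    (OLC) genome assembly and classifies them as true or repeat-induced
    false overlaps before contig construction. Features per overlap include
    alignment statistics (percent mismatch, gaps), k-mer frequency
    statistics (coverage-normalised quartiles, overrepresented and
    singleton k-mers) and a comparative-genomics score obtained by mapping
    both reads of a candidate to a panel of related reference genomes and
    contrasting the best co-placement against the best discordant
    placement. Decision-tree, naive-Bayes and random-forest classifiers
    trained on one data set can be applied to another; overlaps predicted
    false are removed before a minimal unitig-style contigger runs, and
    assemblies are scored by reference-relative N50 and percent of the
    genome matched. A simulator for repeat-rich genomes, diverged related
    strains and error-bearing shotgun reads with known source coordinates
    supports desk-scale benchmarking of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rpart,
    randomForest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
SystemRequirements: C++17
biocViews: Sequencing, Assembly, Classification, Alignment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
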