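Package: phosdomain
Title: Broad Pericentromeric Histone-Phosphorylation Domains and
    Promoter Methyl-Phos Co-Occurrence from Binned ChIP-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of mitotic histone H3 threonine-3 phosphorylation
    (H3T3ph) ChIP-seq alongside H3K4me2/3: Poisson binarization of
    200-bp binned coverage against a depth-scaled input control,
    replicate merging, gap-tolerant calling of one broad
    centromere-proximal domain per chromosome from the largest
    contiguous block of positive bins, a genome-wide positive-bin
    coverage statistic, replicate-consistent peak filtering,
    double-positive bin detection and promoter co-occurrence
    classification within +/- 1 kb of transcription start sites,
    input-normalized ratio tracks, strand-aware reference-point signal
    matrices and metagene profiles, and genome-binned Pearson sample
    correlation.  A seeded synthetic-data generator produces genomes,
    TSS annotations and replicate count tracks with the statistical
    structure the analysis assumes, so every stage is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
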