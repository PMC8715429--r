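Package: near16S
Title: Genome-Linked 16S rRNA Analysis and Semi-Targeted Read Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating the taxonomic discriminatory power of
    genomic regions immediately upstream of the 16S rRNA gene ("near-16S"
    regions) and for the bespoke computational stages of semi-targeted 16S
    sequencing (st16S-seq) read analysis. Extracts 16S rRNA genes with linked
    upstream regions from annotated assemblies, splits genes into
    hypervariable regions V1-V9 by primer matching, computes per-column
    Shannon entropy conservation profiles, quantifies identifiable 16S gene
    copy numbers and identifiable strains, scores OTU clusterings against
    species labels, runs an RDP-style bootstrap naive-Bayes classifier with
    leave-clade-out cross-validation, and implements dereplication,
    swarm-style d-clustering, cluster linkage, contig cleanup, per-OTU
    abundance and copy-number calling for semi-targeted reads. A synthetic
    community generator and read simulator with chain-termination fragment
    lengths provide a self-contained test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
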