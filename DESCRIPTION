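Package: lncSponge
Title: Consensus lncRNA Discovery and Host miRNA Sponge Candidate Detection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for identifying consensus long non-coding
    RNAs (lncRNAs) from multiple de novo transcriptome assemblies of a
    blood-feeding ectoparasite, detecting feeding-regulated lncRNAs by
    negative-binomial exact-test differential expression on TMM-normalized
    expected counts, and ranking lncRNAs as candidate sponges of host miRNAs.
    Candidate sponges are scored by miRNA target-site counts, target density
    per kilobase, and Apriori frequent-itemset mining of recurrent miRNA
    combinations, each compared against a shuffled-sequence null model.
    A synthetic-data module generates inputs with known ground truth
    (planted clusters, open reading frames, fold changes and seed-site
    clusters) so that every stage of the pipeline can be validated by
    planted-structure recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, GeneRegulation, Sequencing, Software
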