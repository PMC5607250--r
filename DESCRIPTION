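Package: duomir
Type: Package
Title: miRNA Discovery and Differential Expression for Paired Small RNA-Seq Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of two pooled small RNA sequencing libraries:
    3' adapter trimming with read accounting, partitioning of unique tags
    against categorized contaminant references (mRNA, Rfam classes, repeats),
    six-group classification of tags against mature and precursor miRNA
    references and a genome, hairpin-based novel miRNA calling with an
    eleven-criterion secondary-structure filter, exact count-based
    differential expression testing with reads-per-million normalization,
    a qPCR 2^-ddCt helper, and construction and export of miRNA-gene-pathway
    regulation networks. A synthetic-data generator plants known ground truth
    (contaminant composition, miRNA identities, hairpin loci, fold changes)
    so every stage can be benchmarked against the truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    igraph,
    stats,
    stringi,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
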