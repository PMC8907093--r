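Package: amfplacer
Title: Phylogenetic Placement of Arbuscular Mycorrhizal Fungi from LSU Amplicons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for identifying arbuscular mycorrhizal
    fungi (AMF, phylum Glomeromycota) in environmental amplicon data from the
    LSU (28S) rRNA gene region. Curates a primer-anchored reference database,
    pre-screens study sequences for homology to the references with a local
    aligner, aligns forward and reverse read fragments separately against
    read-length-cut reference alignments, places queries into a fixed backbone
    phylogeny by minimum-parsimony attachment, and extracts Glomeromycota- and
    family-clade OTU or ASV tables. Includes a synthetic-data generator so the
    whole pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
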