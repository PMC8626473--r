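Package: phylodisc
Title: Gene-Tree Discordance, Introgression Tests and Genome-Duplication Dating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying gene-tree/species-tree discordance and
    distinguishing incomplete lineage sorting from hybridization in phylogenomic
    data sets. Implements a multispecies-coalescent simulator on species trees
    and networks with inheritance probabilities, a rooted topology-type census
    with bootstrap filtering, a triplet branch-length exponential-mixture test
    with a BIC decision rule, ABBA-BABA D-statistics with block-jackknife
    standard errors, a coalescent-simulation false-positive control, and
    node-weighted Ks distributions with weighted-KDE peak detection for dating
    whole-genome duplications and LTR retrotransposon insertions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
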