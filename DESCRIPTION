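Package: urproteome
Title: Phylogenomic Reconstruction of Ancestral Protein Domain Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs upper and lower bounds of the protein fold-superfamily
    (FSF) repertoire of the last universal common ancestor from a genomic census
    of SCOP domain abundance in proteomes. Provides ordered-multistate (Wagner)
    maximum parsimony tree search with Lundberg rooting, most-parsimonious
    ancestral state intervals, iterative refinement of root-branch (plesiomorphic)
    character sets, node-distance timelines with a linear molecular clock,
    superkingdom occurrence classification, hypergeometric enrichment of
    coarse-grained molecular functions, and a gene-content simulator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
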