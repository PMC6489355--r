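Package: crisprCDE
Title: Guide Design, Construct Assembly and Amplicon Genotyping for
    CRISPR-Directed Evolution
Version: 0.1.0
Authors@R:
    person("crisprCDE", "Developers", email = "crisprcde@example.org",
           role = c("aut", "cre"))
Description: Computational toolkit for CRISPR/Cas-directed evolution of
    coding genes. Enumerates every PAM-adjacent protospacer on both strands
    of a coding sequence, designs BsaI Golden-Gate oligo pairs and
    polycistronic tRNA-gRNA (PTG) assemblies, simulates Cas9 cut-and-NHEJ
    repair outcomes with recorded ground truth, and genotypes mutant
    amplicons by affine-gap global alignment into 3'-normalized DNA
    variants and decomposed protein-level consequences (in-frame
    deletions, substitution runs, compound edits, frameshift flags).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
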