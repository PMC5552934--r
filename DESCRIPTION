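Package: copascan
Title: Discovery, Classification and Evolutionary Analysis of Bacterial
    Copper-Transporting P1B-ATPases
Version: 0.1.0
Authors@R:
    person("copascan", "maintainers", email = "copascan@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for surveying copper-transporting P1B-ATPases
    (CopA) and their chaperones (CopZ, CupA, CusF) in multipartite bacterial
    genomes. Candidate transporters are retrieved with a profile hidden Markov
    model built from characterized sequences, placed on maximum-likelihood
    phylogenies (LG+G+F for proteins, GTR+I+G for rRNA) with bootstrap
    support-thresholded clade extraction, assigned to one of six subtypes by
    an explicit motif rule engine over the N-terminal metal-binding domain and
    transmembrane helices 6-8, and screened for horizontal gene transfer by
    closest-homolog criteria, G+C deviation, and codon adaptation index
    against a Monte-Carlo expected CAI. Synthetic-data generators with known
    ground truth make every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    stats,
    tools,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
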