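Package: pepregex
Title: Genetic Programming of Weighted Regular-Expression Models for
    Peptide Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Evolves rule lists of weighted regular expressions that map
    short peptide sequences to a quantitative phenotype, demonstrated for
    chemical exchange saturation transfer (CEST) MRI contrast of 10-13
    residue peptides. Regular expressions are encoded as depth-bounded
    binary trees in heap layout and evolved by genetic programming with
    tournament selection, one-point crossover and structural mutations.
    Rule weights are trained against a sliding-window motif database,
    model fitness is the Pearson correlation between predicted scores and
    measured phenotypes under k-fold cross-validation, and the best
    evolved model drives an in-silico directed-evolution loop that
    proposes candidate peptides filtered by a hydropathy-based
    solubility criterion. A synthetic-data generator with planted motif
    effects makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
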