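Package: speechgraphs
Title: Structural and Semantic Speech Graph Analysis for Psychosis Research
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds network representations of transcribed speech and derives
    graph-theoretic markers of language disorganization and impoverishment.
    Structural (sequential) graphs link each content lemma to the next in
    spoken order; semantic (action-predication) graphs link verb predicates to
    their core arguments and actors to undergoers, as identified by semantic
    role labeling. Nine graph features covering size, connectedness, and
    organization (z-scores against size-matched Erdos-Renyi baselines) are
    computed statically over whole responses and dynamically over moving
    windows, then aggregated to a participant-by-task feature table. Includes
    the accompanying statistical battery (Mann-Whitney U with rank-biserial
    effect sizes, Spearman correlations with clinical scores, Bonferroni
    families, layered stepwise variance-inflation-factor pruning) and a seeded
    synthetic-transcript generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
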