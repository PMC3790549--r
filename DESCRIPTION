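Package: plumevol
Title: Comparative Analysis of Sex-Specific Plumage Evolution on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end comparative pipeline for studying how male and female
    plumage evolve on a molecular phylogeny. Implements unordered (Fitch)
    parsimony with exact enumeration of most-parsimonious reconstructions and
    per-branch unambiguous-change counts, ensemble consistency and retention
    indices, plumage versus molecular p-distance regressions, principal
    coordinate ordination of plumage distances, maximum-likelihood fitting of
    Brownian-motion and single- and multi-optimum Ornstein-Uhlenbeck (Hansen)
    models with AICc model tables, equal-rates Mk reconstruction of ancestral
    geography with marginal node probabilities, and phylogenetically
    independent contrasts of sexual dichromatism against latitude, including
    the branch-length adequacy diagnostic. A synthetic-data module generates
    complete study fixtures (pure-birth trees, Mk-evolved sex-specific
    character matrices, regime paintings, OU traits, Jukes-Cantor sequences,
    latitude metadata) so the whole pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
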