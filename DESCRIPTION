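Package: phylosyndrome
Title: Comparative Phylogenetics of Mating-Syndrome Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring the evolutionary history of discrete
    reproductive syndromes on a phylogeny, motivated by the repeated
    evolution of hypodermic (traumatic) insemination in free-living
    flatworms. Provides rule-based mating-syndrome classification from
    reproductive morphology, constrained Mk models (equal-rates,
    symmetric, all-rates-different, Dollo, ordered, and ordered-Dollo
    templates) with maximum-likelihood fitting and AICc model comparison,
    Bayesian stochastic character mapping with transition-count summaries
    and a conservative lower-bound rule for counting independent origins
    of a derived state, Pagel's test of correlated evolution between
    binary characters with stepping-stone marginal likelihoods and Bayes
    factors, phylogenetic principal component analysis under a Pagel's
    lambda model, weighted phylogenetic generalized least squares with
    predictive R-squared, and a synthetic-data generator producing trees,
    discrete character histories and correlated continuous traits with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    Matrix,
    coda,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite
Config/testthat/edition: 3
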