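Package: amphievo
Title: Comparative Molecular-Evolution Toolkit for Amphibian Ortholog Sets
Version: 0.1.0
Authors@R: person("amphievo", "maintainers", email = "maintainers@amphievo.org",
    role = c("aut", "cre"))
Description: Tools for comparative molecular-evolution analyses of
    one-to-one ortholog sets across amphibians and other vertebrates:
    supermatrix quality filtration (completeness, RCFV compositional
    heterogeneity, chi-square and Bowker matched-pairs symmetry tests),
    evaluation of fixed species-tree hypotheses by per-site
    log-likelihoods and the approximately-unbiased (AU) test, supertree
    construction by genes-as-characters step-matrix parsimony and
    multispecies-coalescent triplet pseudo-likelihood, branch and
    branch-site codon-model selection scans (dN/dS), rapidly evolving GO
    category detection, parallel and convergent amino-acid substitution
    analysis with chance probabilities, Rate4Site-style site conservation
    profiles with cubic smoothing splines, and qPCR delta-delta-Ct
    relative quantification.  A synthetic-data module generates every
    input the pipeline consumes so all analyses are testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
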