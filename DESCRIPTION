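Package: ligandblend
Title: Blended Ensemble Classification of Receptor-Ligand Functional Activity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Three-class classification of ligand functional activity
    (antagonist, agonist, allosteric modulator) for receptor-ligand pairs.
    Provides curation of multi-source interaction tables including z-score
    deduplication of replicate Ki binding affinities, zero-variance
    descriptor filtering, assembly of per-pair feature vectors from ligand
    descriptor and receptor embedding tables, ligand-disjoint dataset
    splitting, Bemis-Murcko scaffold diversity audits with Shannon entropy,
    a blending ensemble in which base-learner class probabilities become
    meta-features for a second-stage metamodel, per-receptor frequency and
    Tanimoto-similarity baselines, imbalance-aware multi-class evaluation,
    and a synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    igraph,
    xgboost,
    ranger,
    nnet,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
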