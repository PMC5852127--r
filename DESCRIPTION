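Package: VarStab
Title: Stability-Driven Classification of Non-Synonymous Protein Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives knowledge-based statistical mean-force potentials from
    sets of protein three-dimensional structures and uses them to score and
    classify single amino-acid substitutions as deleterious or neutral.
    Implements generic inclusion-exclusion potentials over sequence and
    structure descriptors (residue type, solvent accessibility, backbone
    torsion domain, side-chain distance), solvent-accessibility-gated linear
    models for folding free-energy and melting-temperature changes, a
    sign-split gated index that flags both stabilizing and destabilizing
    deleterious variants, a probabilistic neural network classifier with
    per-feature bandwidths, and a linear meta-combiner with an external
    evolutionary conservation score. Includes balanced-accuracy threshold
    optimization, mutation- and protein-level cross-validation, dataset
    filtering rules, and a synthetic structure/variant generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    yaml,
    pROC,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'config.R'
    'structure-io.R'
    'structure-descriptors.R'
    'potentials.R'
    'stability.R'
    'pathogenicity.R'
    'evaluation.R'
    'trainers.R'
    'fixtures.R'
    'pipeline.R'
    'show-methods.R'
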