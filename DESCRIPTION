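Package: afpred
Title: Antifreeze Protein Prediction from Hybrid Sequence Descriptors with
    Undersampling Random-Forest Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies antifreeze proteins (AFPs) from protein sequences.
    Encodes each sequence as a 329-dimensional hybrid descriptor built from a
    ten-functional-group reduced alphabet (amino-acid and dipeptide
    composition), global physicochemical parameters and auto-covariance
    pseudo amino-acid composition, per-residue intrinsic-disorder summaries,
    binary InterPro domain indicators and functional-group-reduced PSSM
    evolutionary features. Severe class imbalance is handled by undersampling
    the majority class into G balanced subsets, training one random forest
    per subset and predicting by majority vote. Features are ranked by the
    two-group ANOVA F statistic and pruned by incremental feature selection
    scored with stratified 10-fold cross-validated balanced accuracy.
    Includes synthetic sequence/PSSM/disorder/domain generators and
    simulation experiments for imbalance-ratio, ensemble and dataset-size
    effects.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    ranger
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'alphabet.R'
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'afpred-package.R'
    'descriptors-pssm.R'
    'descriptors-domain.R'
    'descriptors-disorder.R'
    'descriptors-physchem.R'
    'descriptors-composition.R'
    'assemble.R'
    'evaluation.R'
    'ensemble.R'
    'feature-selection.R'
    'io-fasta.R'
    'synthetic.R'
    'experiments.R'
    'filter-split.R'
    'io-pssm.R'
    'io-tables.R'
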