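Package: dbpboost
Title: DNA-Binding Protein Prediction with Physicochemical Sequence
    Features and Imbalance-Aware Boosting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies DNA-binding proteins from amino-acid sequence
    alone.  Each protein is encoded as a 188-dimensional feature vector
    combining amino-acid composition with content, distribution and
    dipeptide-composition descriptors computed over eight
    physicochemical groupings of the 20-letter alphabet.  Classification
    uses an imbalance-aware boosting ensemble: every round keeps all
    positive (DNA-binding) examples, draws an equally sized set of
    negatives from an adaptively re-weighted distribution, trains one of
    a roster of twenty heterogeneous base classifiers, and combines the
    rounds by weighted vote.  Includes confusion-matrix metrics
    (sensitivity, specificity, accuracy, MCC, F1), a synthetic sequence
    generator with tunable class-compositional shift and imbalance, a
    negative-sample-count sweep experiment, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    class,
    e1071,
    glmnet,
    MASS,
    nnet,
    randomForest,
    ranger,
    rpart,
    stats,
    tree,
    utils,
    xgboost
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
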