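Package: varmoi
Title: Pathogenicity and Mode-of-Inheritance Classification for
    Nonsynonymous Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates nonsynonymous single-nucleotide variants with
    evolutionary, allele-frequency, functional, network and gene-level
    features and classifies each variant into benign, dominant and
    recessive classes with a three-class random forest, returning one
    probability per class.  Includes the full training protocol
    (per-gene sampling of training pools, -1/+1 encoding of descriptive
    features, weighted three-class imputation of missing values),
    repeated stratified 10-fold cross-validation with Hand-Till
    multiclass AUC and per-class precision/recall, out-of-bag
    permutation importance, and a synthetic fixture generator (toy
    genome, transcript models, resource tables and class-labelled
    variant pools with tunable class separation) so the whole pipeline
    can be exercised offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    data.table,
    igraph,
    jsonlite,
    randomForest,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
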