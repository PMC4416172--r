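Package: milbind
Title: Multiple-Instance Learning on DNA Structural Features for TF-DNA
    Binding Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts in vitro transcription factor binding to
    protein-binding-microarray probes by multiple-instance learning over
    trinucleotide structural parameters of DNA (shear, buckle, stretch,
    propeller, stagger, opening). Each probe is decomposed into a bag of
    overlapping k-mer instances; a wrapper algorithm trains a
    weighted-instance decision tree on the flattened instances and scores a
    probe by averaging instance class probabilities, which also localizes
    putative binding sites. Includes single-instance structural and
    k-mer-counting baselines, AUC benchmarking with top-k-mer and
    gain-correlation analyses, and a seeded synthetic-data generator with
    planted motifs and structural twin motifs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    rpart,
    jsonlite,
    optparse,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
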