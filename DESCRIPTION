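Package: phenossu
Title: Fine-Grained Phenotype Knowledge Graphs with an Entity-Attribute-Value Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building fine-grained phenotype knowledge graphs from
    clinical-guideline text with a semantic structured unit model: a phenotype
    concept plus a fixed, SNOMED-CT-coded set of twelve attributes (presence,
    manifestation and spatial categories) with closed value sets. Includes a
    bit-exact reader/writer for BRAT standoff annotation with dual-annotation
    merging and agreement marking, sentence-level co-occurrence mining of
    candidate attributes, a dictionary-based phenotype concept recognizer with
    an adapter for external recognizers, per-attribute support-vector value
    classifiers over trigger-term presence/distance features with minority
    oversampling and grid-searched hyperparameters, overlap-based span
    evaluation and imbalance-aware weighted-accuracy metrics, an expressiveness
    comparison of information-model profiles, and a seeded generator of
    guideline-like corpora with exact gold annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
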