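Package: kdsucc
Title: Multi-Teacher Knowledge Distillation for Lysine Succinylation Site Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts lysine succinylation sites from protein sequence windows
    with a dual-teacher knowledge-distillation framework. Lysine-centered
    33-residue fragments are tokenized over a 21-symbol amino-acid vocabulary,
    embedded with a trainable word-embedding layer, and classified by a compact
    hybrid CNN/Bi-LSTM student network trained to match both hard labels and the
    temperature-softened output distributions of two pre-trained teacher
    networks (a Conv1D stack and a Bi-LSTM stack). Includes fragment
    extraction with pseudo-residue padding, greedy identity-based redundancy
    filtering, class-ratio-aware dataset assembly, a synthetic motif benchmark
    generator, confusion-matrix metrics (sensitivity, specificity, accuracy,
    Matthews correlation coefficient), stratified k-fold cross-validation, an
    alpha/temperature ablation harness, positional residue enrichment, t-SNE
    feature projection, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    Rtsne,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
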