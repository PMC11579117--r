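Package: neurotype
Title: Cross-Species Neuronal Cell-Type Classification from
    Electrophysiological Features
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies neurons from tabular electrophysiological features
    using two complementary neural models. A domain-adversarial network
    (gradient-reversal training) transfers information from data-rich mouse
    recordings to scarce human recordings for broad-type (excitatory vs.
    inhibitory) prediction, and a locally sparse, per-sample gated network
    classifies five transcriptomic subclasses (Glutamatergic, Pvalb, Sst,
    Vip, Htr3a+|Vip-) while exposing, through its gate matrix, which
    features drove each prediction. Includes a seeded synthetic-cohort
    generator with known informative-feature structure and controllable
    domain shift, a preprocessing pipeline (line merging, NaN filtering,
    stratified splitting, train-statistic normalization), macro-averaged
    evaluation utilities, cross-species ablations, and a reproducible
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pheatmap
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
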