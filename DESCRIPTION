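Package: promsig
Type: Package
Title: Spatial Promoter Recognition Signatures for Transcription Factor Targets
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generative hidden Markov models of transcription factor
    binding-site position, orientation and density within promoters
    ("promoter recognition signatures").  Provides exact inference by
    message passing in log/odds space, maximum-likelihood training by
    expectation-maximization with analytic and simulated-annealing
    M-steps from multiple starts, likelihood-ratio and segment-swap
    scrambling controls, an unbound-region screen, sampling-based
    Kullback-Leibler specificity estimates with an exact small-model
    oracle, thermodynamic / top-site / signature target rankers with
    resampling-based evaluation statistics, and a synthetic promoter
    benchmark generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    methods,
    stats,
    utils,
    yaml,
    Biostrings,
    pROC,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
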