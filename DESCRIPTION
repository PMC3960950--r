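Package: igsom
Title: Interconnected Growing Self-Organizing Maps for Joint Auditory and
    Semantic Category Acquisition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements interconnected growing self-organizing maps (I-GSOM):
    two dynamically growing neural lattices -- one auditory, one semantic --
    coupled by trainable, forgettable associative links, as a model of how
    sound and meaning categories are acquired jointly from paired input.
    Provides accumulated-error node growth, Gaussian neighborhood updates
    with node-count-dependent learning-rate decay, cyclical reinforcing /
    reviewing / reinforcing-by-link training schedules, a non-mutating
    checking (calibration) pass with perceiving-path link accuracy, a
    Bark-scale auditory preprocessing pipeline for annotated syllable
    recordings, and a synthetic acoustic-semantic corpus generator for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    yaml,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'gsom-core.R'
    'links.R'
    'training.R'
    'checking.R'
    'preprocess.R'
    'preprocess-io.R'
    'synthetic.R'
    'io.R'
    'cli.R'
    'igsom-package.R'
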