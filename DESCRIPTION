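Package: snrthresh
Title: Partition Fitness and Threshold Selection for Functional Connectomes via Stochastic Block Model Signal-to-Noise
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how prominently an a-priori set of functional
    sub-circuits (communities) is expressed in weighted functional
    connectomes, using the signal-to-noise ratio (SNR) of the stochastic
    block model community profile matrix. The SNR, compared against the
    Kesten-Stigum weak-recovery threshold, vets and selects connectome
    thresholds at the group-average and individual-subject level. Includes
    partition-shuffle null models, a community-detection back-test
    (modularity maximization and Poisson SBM inference compared by adjusted
    mutual information), and a synthetic planted-partition cohort generator
    so every stage is exercisable without restricted neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
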