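Package: nvctf
Title: Transfer-Function Modeling of Neurovascular Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits shifted-gamma impulse-response transfer functions linking
    neuronal activity traces (dendritic calcium, LFP gamma-band power) to
    vascular response traces (capillary red-blood-cell velocity, power-Doppler
    cerebral blood volume) using a stochastic simulated-annealing protocol
    with multi-start iterative restarts. Provides signal preprocessing
    (shape-preserving interpolation, baseline normalization, fit windowing),
    convolution-based response prediction with post-hoc amplitude rescaling,
    self- and leave-one-out cross-validation across a cohort with standard
    transfer-function selection, decomposition of delayed secondary vascular
    components with two-kernel combined predictions, area-under-curve voxel
    ranking, and a synthetic trial generator with known ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
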