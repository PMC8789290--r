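Package: iftcargo
Title: Stochastic Cargo Loading on Intraflagellar Transport Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of two-color TIRF imaging of cargo
    transport by intraflagellar transport (IFT) trains in Chlamydomonas
    flagella. Provides a train-traffic and cargo-loading simulator for two
    competing models of IFT-cargo interaction (loading restricted to a
    specialized subclass of trains versus stochastic loading onto any train),
    a photobleaching-aware synthetic two-channel kymograph renderer, a
    kymograph track extractor with transport-event measurement, the
    cotransport probability statistic with exact and permutation independence
    tests and model-discrimination power analysis, and a paired long-short
    flagella frequency-versus-length-difference analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
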