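Package: decrates
Title: Time-Stratified Dispersal-Extinction-Cladogenesis Models and
    Biogeographic Stochastic Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood inference of geographic range evolution on
    time-calibrated phylogenies under the dispersal-extinction-cladogenesis
    (DEC) model and its DIVALIKE and BAYAREALIKE variants, with
    time-stratified (epoch-specific) dispersal multiplier matrices.
    Provides marginal ancestral range estimation, biogeographic stochastic
    mapping by endpoint-conditioned Markov path sampling, per-time-bin
    dispersal and in situ speciation rate statistics (colonization,
    emigration, immigration and speciation rates through time), tree
    pseudoreplication (node-age jitter and grafting of unsampled tips),
    and a forward simulator of range evolution for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
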