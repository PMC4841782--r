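Package: slalom
Title: Turn-Sequence Structure and Neural Tuning of Zebrafish Exploratory Locomotion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for spontaneous swimming in larval zebrafish:
    bout detection and signed turn-angle extraction from trajectory
    recordings, streak (turn-state) statistics against bias-matched
    coin-flip nulls, decoding of signed turns from two-channel fictive
    motor-nerve recordings, voxel-wise behavioral-tuning regression of
    volumetric calcium imaging with a raised-cosine polar basis, a
    two-state hidden Markov model of turn direction fitted by Baum-Welch,
    and a foraging-efficiency simulator comparing correlated and
    uncorrelated turning strategies. Seeded synthetic-data generators
    emulate all three input modalities so every stage is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    zoo,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    tiff,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
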