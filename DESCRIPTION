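Package: mesochela
Title: Cheliceral Biomechanics and Feeding-Habit Classification for
    Free-Living Mesostigmatid Mites
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Lever mechanics of the mesostigmatid cheliceral chela: derived
    quantities per specimen (velocity ratio, aspect ratio, morphological
    crunch-force indices), harmonisation of historical morphometric data sets
    via published regression constants, log-log allometric power-law fits,
    correlation-matrix principal component analysis of log morphometrics with
    an isotropy pre-multiplier, cephalisation classification from gnathosomal
    width residuals, a probabilistic velocity-ratio classifier of feeding
    habit (worm-like prey "crusher" versus micro-arthropod "cutter") with ROC
    summaries, heuristic verbal trophic profiles, habitat over-representation
    z-tests, bundled study tables as validated plain-text fixtures, and a
    seeded synthetic-data generator for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
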