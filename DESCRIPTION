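Package: syntheff
Title: Synthesis Efficiency and Overall Yield of Branched Synthesis Routes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents convergent and branched chemical syntheses, including
    multicomponent reactions, as recursive route trees and evaluates them with
    the step-count-weighted branch-averaging yield algorithm. Computes overall
    yields, synthesis efficiency (overall yield per synthesis step), parallel
    reaction modification factors, fictive fully-sequential yields, a simple
    step-based cost model, fragment-condensation strategy comparisons, and an
    average-yield/step-number efficiency grid. Routes can be read from and
    written to a small YAML-based file format; a command-line front end covers
    evaluation, validation, comparison, tabulation, and random route
    generation for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
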