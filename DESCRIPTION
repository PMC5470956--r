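Package: circaDisrupt
Title: Profiling Circadian Transcriptome Disruption in Two-Condition Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising how a perturbation (e.g. a tumor burden)
    rewires circadian gene expression in a two-condition zeitgeber-time course.
    Provides a JTK-style nonparametric rhythmicity test with an exact
    permutation null, reliable-cycler set construction against a reference
    list, per-timepoint differential ranking with fold-change criteria,
    closed-form fixed-period cosinor regression with circular acrophase
    differences, a decision-tree taxonomy of disruption phenotypes (uniform
    change, phase advance or delay, amplitude change, rhythm loss, day-night
    reversal), and a seeded synthetic-data generator with planted per-gene
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
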