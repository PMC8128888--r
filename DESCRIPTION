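Package: capmap
Title: Cochlear Frequency-Place Map Inference from CAP Reduction Times
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for apex-to-base cochlear perfusion
    experiments in the guinea pig.  Converts the perfusion times at which
    tone-evoked compound action potentials (CAPs) are reduced into cochlear
    place and characteristic frequency via a Greenwood-type frequency-place
    map, builds CAP reduction-time tuning curves (80/50/20 percent reduction
    times across stimulus level), and tests operated-versus-control group
    differences in 50 percent reduction times with exact and Monte-Carlo
    label-permutation tests, including two multi-frequency grand-average
    combination schemes.  Also provides waveform-level CAP, ANOW and
    otoacoustic-emission (DPOAE/SFOAE) amplitude extraction with
    standard-error noise floors, and a seeded synthetic-data generator that
    reproduces the study's statistical structure (correlated ear effects,
    non-responding ears, sigmoidal amplitude declines) so that every
    pipeline stage is testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
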