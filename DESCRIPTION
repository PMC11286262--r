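Package: spikesig
Title: Spike-Train Signatures of Cerebellar Movement Disorders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Interspike-interval analysis of 30-second awake recordings from
    cerebellar nuclei neurons. Computes twelve spike-train parameters (rate,
    irregularity, pause and rhythmicity statistics including CV2 and an
    autocorrelogram-based rhythmicity index), fits a coarse Gini decision
    tree (at most three splits) that assigns control, ataxia, dystonia or
    tremor spike signatures, runs the cohort-level statistics used to compare
    disease models (two-proportion z-tests, enrichment chi-square, one-way
    ANOVA with Tukey-Kramer post hoc, Hann-window tremor power spectra), and
    ships a synthetic spike-train generator that emulates the four archetypal
    phenotypes and the optogenetic stimulation paradigms so the whole
    pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
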