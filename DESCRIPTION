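Package: dielrhythm
Title: Diel Rhythm Analysis for Locomotor Activity and Transcriptome Time
    Courses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects and characterizes ~24-hour (diel) rhythms in animal
    behavior and gene expression. Provides hourly binning and per-individual
    normalization of locomotor tracking records, a dense-grid discrete-Fourier
    periodogram with permutation significance for sub-hour period estimates,
    day/night activity summaries and daily-peak phase-shift reports; an
    RNA-seq arm with aligned-read filtering and start-position
    de-duplication, trimmed-mean-of-M-values normalization weighted by
    inverse Poisson standard deviations, replicate concordance against the
    99% Poisson region, a spectral g-factor rhythmicity screen, K-means phase
    clustering and peak Zeitgeber-time estimation; cross-species homolog
    day/night fold-change filtering; and seeded synthetic-data generators for
    activity cohorts and Poisson count time courses with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
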