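Package: gfconn
Title: Global Functional Connectivity Change Analysis for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for detecting session-to-session changes in
    resting-state functional connectivity from parcel time series. Computes
    per-region global connectivity (gFC, and its positive-only and
    negative-only components) from Fisher-Z transformed Pearson correlation
    matrices, screens per-parcel session deltas with one-sample t-tests under
    Benjamini-Yekutieli (or Benjamini-Hochberg) FDR control, validates
    detections against a fixed positive-connection set, follows up with
    seed-restricted per-connection change tests, and relates connectivity
    changes to behavioral and volumetric measures via Spearman correlation.
    Includes the standard signal-cleaning chain (volume trimming, ideal FFT
    band-pass, gray-matter-masked parcellation, nuisance regression, framewise
    displacement motion QC) and a synthetic multi-subject two-session data
    generator with planted connectivity effects that provides ground truth for
    calibration and power checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    RNifti,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
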