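Package: sfxsad
Title: Scaling, Merging and Anomalous-Signal Analysis of Serial
    Crystallography Still Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Data-treatment procedures for single-wavelength anomalous
    diffraction (SAD) phasing of serial femtosecond crystallography (SFX)
    still data: Monte Carlo merging of partial still intensities with
    two-pass per-image scaling, detector-distance and tile-geometry
    refinement driven by unit-cell statistics, half-dataset quality
    metrics (R_split, CC1/2, CC*, R_ano, CC_ano), correlation-based image
    selection, anomalous difference Patterson and Fourier analysis by
    direct summation, and consensus filtering of heavy-atom substructure
    solutions under origin and hand ambiguity.  A synthetic still-image
    simulator with a recoverable ground truth exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    mclust,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
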