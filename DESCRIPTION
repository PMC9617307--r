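Package: mrlap
Title: Quantitative Left Atrial Pressure from Mitral Regurgitation Doppler Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Noninvasive, quantitative estimation of left atrial pressure (LAP)
    from the continuous-wave Doppler spectrum of a mitral regurgitation jet.
    Implements the equation-based estimator (LAP_Eq) that solves a Weiss
    mono-exponential left-ventricular relaxation model coupled with the
    simplified Bernoulli pressure mapping for LAP and the relaxation time
    constant tau, using the times at which the descending branch of the jet
    envelope crosses 1, 2 and 3 m/s; the sphygmomanometer reference method
    (LAP_BP = systolic arterial pressure minus peak regurgitant gradient); a
    spectrogram envelope-extraction pipeline (column-wise edge detection with
    robust polynomial refinement and calculability rules); a ground-truthed
    synthetic spectrogram generator with speckle noise and eccentric-jet
    velocity underestimation; and a paired method-comparison statistics
    harness (paired t, Fisher-z correlation intervals, 10 percent consistency
    grouping, chi-square, rank-sum, intraclass correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
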