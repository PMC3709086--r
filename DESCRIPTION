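Package: vitaldrift
Title: Distribution Drift and Novelty Detection in Post-Operative Vital Signs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing trajectories of ward vital-sign observations
    (heart rate, respiratory rate, SpO2, systolic blood pressure, tympanic
    temperature) during post-operative recovery. Quantifies distribution drift
    across a patient's stay with Kolmogorov-Smirnov, symmetric
    Kullback-Leibler and Bhattacharyya distances between daily-average
    subgroups; visualises recovery with a Sammon nonlinear projection; and
    detects physiological deterioration with a kernel-density model of
    normality scored by a negative log-likelihood novelty score with a
    mean-plus-three-standard-deviations alarm threshold. Includes a synthetic
    cohort generator that emulates the admission-to-discharge statistical
    structure of such data for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0), MASS, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
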