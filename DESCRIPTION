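Package: gelkin
Title: Quantification of Aggregate Dynamics, Cluster Fusion and Hydrogelation Kinetics in Phase-Separating Amyloid Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory-based quantification of the stages beyond liquid-liquid
    phase separation in amyloid systems such as human islet amyloid polypeptide
    (hIAPP): single-particle tracking with mean-flow subtraction, mobility-arrest
    gelation timing, co-movement connectivity graphs, aggregate-cluster lineage
    tracking with fusion onset and completion quantitation, oscillatory rheology
    feature extraction (lag, rate, plateau, tan delta, kinetic regime, frequency
    sweep gel criterion), replicate-heterogeneity profiling by coefficient of
    variation, and hard-sphere excluded-volume crowding arithmetic. A synthetic
    particle-field and rheology generator with known ground truth makes every
    stage testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
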