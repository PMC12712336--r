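Package: myrmimic
Title: Mimicry-Accuracy Scoring and Macroevolutionary Model Fitting for
    Ant-Mimicking Arthropods
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies myrmecomorphy (ant mimicry) from specimen
    biometrics via a nine-trait accuracy index, and analyses its
    macroevolution on time-calibrated phylogenies: maximum-likelihood
    fitting and AICc comparison of Brownian motion, Ornstein-Uhlenbeck,
    early-burst and white-noise models; a bounded trait-diffusion (FPK)
    model with a quartic evolutionary potential and its adaptive
    landscape; ancestral character estimation by rerooting
    model-transformed trees; phylogenetic signal (Pagel's lambda,
    Blomberg's K); replication of all fits across posterior tree samples;
    and a synthetic-data generator (birth-death trees, trait simulation
    under every fitted model class, measurement-table synthesis) so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
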