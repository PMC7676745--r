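Package: aaarisk
Title: Probabilistic Rupture Risk Assessment for Abdominal Aortic Aneurysms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Patient-specific, probabilistic quantification of abdominal
    aortic aneurysm (AAA) rupture risk from clinical data. Provides a
    correlated multi-output Gaussian-process regression model that predicts
    the joint distribution of invasive vessel-wall properties (wall
    thickness, two stiffness parameters and wall strength) from eight
    non-invasive clinical features, a universal Kriging surrogate of a
    wall-stress forward model with an explicit trilinear trend and an
    active-learning training loop, Monte-Carlo estimation of the
    probability of rupture, deterministic and cohort-based comparator
    indices (RPI, PRRI), a seeded synthetic-cohort generator, and a
    case-control evaluation layer with group summaries, relative
    differences and ROC/AUC analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    lhs,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
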