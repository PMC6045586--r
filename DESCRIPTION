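Package: cotreach
Title: Cost-of-Time Analysis of Self-Paced Reaching Movements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study movement vigour and the implicit cost of time in
    self-paced, single-joint arm reaching. Provides a linear-quadratic
    fixed-time optimal control solver for a torque/jerk effort cost, inverse
    optimal control identification of a sigmoidal cost-of-time function from
    amplitude-duration data, minimum-jerk segmentation of shoulder-angle
    recordings, vigour scoring, three-level variance decomposition of vigour
    via mixed models, trait regressions, and a synthetic cohort generator so
    that the full pipeline can be exercised and validated without access to
    raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
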