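Package: reachkin
Title: Reach-to-Grasp Kinematics, Motor Flexibility and Sustained-Attention
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing three-marker motion-capture recordings of
    reach-to-grasp movements: zero-phase low-pass Butterworth filtering,
    velocity-threshold movement segmentation, extraction of eleven transport
    and grip kinematic parameters (peak wrist velocity and deceleration,
    trajectory deviation, grip aperture and closing velocity, and their
    movement-time-normalised peak times), a max-minus-min Range index of
    motor flexibility, loglinear-corrected d-prime for continuous performance
    test data, and the matching inferential layer (linear mixed models with
    Satterthwaite degrees of freedom, Bonferroni post hocs, planned contrasts,
    regressions on years of practice). A minimum-jerk synthetic trial and
    cohort generator with exported ground truth supports end-to-end validation
    without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    emmeans,
    lme4,
    lmerTest,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
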