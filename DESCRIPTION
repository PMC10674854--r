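Package: tapscore
Title: Clinically Aligned Severity Scoring of Finger-Tapping Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated assessment of bradykinesia from the MDS-UPDRS finger
    tapping task using 3D hand-landmark time series. Converts 21-point hand
    keypoints to a palm-normalized thumb-index distance signal, cleans it with
    empirical mode decomposition, local polynomial smoothing and
    prominence-based peak detection, extracts fifteen clinically aligned
    kinematic and demographic features (amplitude and velocity statistics,
    piecewise-linear decrement parameters, halt/hesitation counts, tapping
    frequency), and classifies severity 0-4 with an interpretable decision
    tree alongside a rule-based classifier that operationalizes the MDS-UPDRS
    rating criteria literally. A synthetic tapping simulator with
    severity-graded impairment profiles makes the full pipeline testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
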