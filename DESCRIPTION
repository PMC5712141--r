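Package: gaitassist
Title: Detecting and Characterizing Therapist Balance Assistance from Sacral Accelerometry
Version: 0.1.0
Authors@R:
    person("Gaitassist", "Developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying manual balance assistance provided by
    physical therapists during overground gait training, and for predicting
    the timing of those assistance events from a single sacrum-mounted
    accelerometer. Implements the force-characterization pipeline
    (Butterworth low-pass filtering, baseline removal, two-hand resultant
    force, per-event peak, duration and impulse), a Tukey-fence outlier
    detector on the smoothed free-acceleration resultant, event matching
    with temporal tolerance and PPV/TPR scoring, an (alpha, delta) grid
    search with development/validation splitting, and a seeded simulator of
    therapist-patient training sessions so the whole method is testable
    without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
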