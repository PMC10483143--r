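Package: soundarena
Title: Closed-Loop Sound-Arena Place-Preference Assay: Simulation, Replay and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the "sound arena" auditory place-preference/avoidance
    assay, in which a mouse's real-time position in a four-quadrant open field
    determines which tone (or silence) is played. Provides the closed-loop
    position-to-soundscape engine with habituation gating and debounced tone
    switching, centroid tracking from grayscale frame stacks, trajectory file
    input/output, the full behavioral readout pipeline (per-quadrant occupancy,
    preference indices, binned time courses, area under the curve, distance
    traveled, heat maps), the accompanying statistical battery (Student's t,
    one-way ANOVA with Tukey HSD, two-way repeated-measures ANOVA), and
    agent-based and dwell-process trajectory simulators so that every stage of
    the pipeline can be exercised and calibrated without animal data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
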