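Package: lcbehave
Title: Lattice-Computing Analysis of Behavioral States in Child-Robot
    Interaction Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for behavioral phenotyping from robot-logged session
    data. A face observed as 68 planar landmarks is represented as a
    59-node hierarchical tree of nose-normalized polar features; a
    parametric lattice-computing distance over such trees (trivial or
    interval-valued) supports nearest-prototype head-pose classification,
    genetic-algorithm tuning of the 126 metric weights, and k-means
    induction of nine behavioral states. Four analysis tools relate
    robot-action events (Animation, Sound, LEDs, Speaking) to the child's
    state dynamics: modality-conditional state histograms, event-triggered
    state-transition counting, state time-series visualization, and
    run-collapsed sequence-pattern mining. A synthetic-data generator
    emulates pose-dependent landmark geometry and scripted session logs
    with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
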