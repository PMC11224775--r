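Package: fnirsprobe
Title: Probe Geometry, Multiplexing Schedules, and IMU-Based Shape
    Estimation for Modular fNIRS Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Design and acquisition-planning toolkit for modular functional
    near-infrared spectroscopy (fNIRS) probes built from diamond-shaped
    optode modules. Models module geometry and intra-module channels,
    represents module-to-module connection topology, enumerates
    source-detector channels under a separation threshold, assigns spatial
    multiplexing groups by conflict-graph coloring and predicts acquisition
    frame rates, and reconstructs three-dimensional optode positions from
    per-module orientation-sensor quaternions with a piece-wise spherical
    surface model. Includes a synthetic-data generator that places probes on
    analytic surfaces with known ground truth, evaluation metrics against
    digitized positions, and SNIRF-compatible probe export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
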