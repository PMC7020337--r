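Package: cbsnn
Title: Curiosity-Based Training of Conductance Spiking Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates three-layer conductance-based leaky integrate-and-fire
    (LIF) spiking neural networks and trains them for classification with a
    two-stage membrane-potential tuning rule (feed-forward dynamics blended
    with an equilibrium-state correction), a supervised teacher clamp on the
    output layer, and a bilinear STDP weight update. A curiosity scheduler
    scores every training sample by the cosine distance between its output
    potentials and its teacher signal ("novelty"), repeatedly retrains only
    samples above a novelty threshold, and periodically reviews the full
    dataset, cutting total sample presentations while preserving accuracy.
    Includes IDX and CSV dataset readers, a synthetic Gaussian-cluster
    generator with controllable class overlap, an experiment harness for
    strategy comparisons and one-at-a-time hyperparameter sweeps, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
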