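Package: saec
Title: Spiking Active Efficient Coding for Event-Based Vision
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully spiking implementation of active efficient coding for
    event-camera input. A two-layer unsupervised spiking encoder (simple and
    complex cells with spike-timing-dependent plasticity, weight sharing and
    static, lateral and top-down inhibition) learns a sparse representation of
    an event stream. The learned plastic inhibition lowers population activity
    for frequently seen stimuli, yielding an intrinsic reward that drives a
    continuous-time spiking actor-critic (reward-modulated STDP with
    eligibility traces) to learn visual tracking and orientation-stabilization
    behaviours. Includes a frame-to-event emulator, Ornstein-Uhlenbeck camera
    jitter, synthetic closed-loop environments rendered at 1 kHz, staged
    training, checkpointing and reporting utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
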