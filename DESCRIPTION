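Package: fdmachine
Title: Causal-State Models of Short-Term Synaptic Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a calcium-dependent facilitation-depression model of
    short-term synaptic plasticity driven by Poisson spike trains, derives the
    closed-form stochastic fixed-point distributions of the normalized
    postsynaptic response for the depressing synapse, and characterizes the
    response process with computational mechanics: binary symbolization of
    response trains, epsilon-machine reconstruction with the Causal State
    Splitting Reconstruction (CSSR) algorithm, and statistical complexity of
    the reconstructed machines across firing rates.  Includes deterministic
    fixed-point analysis of the map, a maximum-complexity threshold selection
    procedure, machine validation and comparison utilities, and an end-to-end
    experiment driver producing complexity spectra for depressing,
    facilitating and mixed synapse presets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
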