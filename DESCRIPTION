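Package: polywm
Title: Polychronous Spiking Networks and Spike-Timing Working Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and analysis toolkit for working memory maintained by
    spike timing in delayed spiking networks. Builds networks of simple
    two-variable spiking neurons with per-synapse axonal conduction delays,
    long-term spike-timing dependent plasticity (STDP) acting on presynaptic
    arrival times, and two interchangeable associative short-term mechanisms
    (short-term STDP with seconds-scale decay, and a hysteretic NMDA-spike
    synapse mode). Polychronous neuronal groups (PNGs) can be discovered from
    network structure, engineered and inserted, cued into working memory, and
    detected as template reactivations in spike rasters. Includes the
    experiment protocols (single and multi-item cueing, novel-cue learning,
    neuromodulated gating, memory erasure) and the spike-train measurement
    battery (multiunit rates, ISI CV and CV2, cross-correlograms, working
    memory duration and capacity curves).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
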