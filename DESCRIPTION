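Package: zebracpg
Title: Spinal Locomotor Circuit Models of the Developing Zebrafish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spiking-network models of the spinal central pattern generators that
    drive the locomotor movements of developing zebrafish: single coiling, double
    coiling, and beat-and-glide swimming. Networks of single-compartment Izhikevich
    neurons are coupled through gap junctions and distance-delayed chemical synapses
    and drive a simplified musculoskeletal body model (muscle cells as passive RC
    circuits forcing a chain of uncoupled damped pendulums). Includes in-silico
    population silencing and transmitter-blockade protocols, Gaussian parameter-noise
    sensitivity batteries, and kinematic analysis of the simulated motor output
    (swim episodes, tail-beat frequencies, coil classification, phase delays, and
    left-right alternation).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
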