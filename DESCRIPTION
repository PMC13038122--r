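Package: tmskernels
Title: Coupling TMS-Induced Electric Fields to Neural Population State
    Variables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-stage biophysical coupling model from transcranial
    magnetic stimulation (TMS) induced electric fields to mean-field
    neural state variables. Stage one exposes compartmental
    Hodgkin-Huxley cable models of presynaptic neurons to parameterized
    electric fields via extracellular quasipotentials and summarizes the
    resulting action-potential arrivals at axon terminals as axonal delay
    kernels, i.e. spike-density functions over cortical depth and time.
    Stage two converts those kernels into conductance-based synaptic
    drive on postsynaptic dendritic trees and measures the mean dendritic
    current entering the soma. A generalized polynomial chaos surrogate
    with anisotropic truncation provides fast prediction plus
    time-resolved Sobol and derivative-based sensitivity analysis over
    the field and synapse parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
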