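Package: wormCPG
Title: Network Pattern Generators for C. elegans Forward Locomotion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Neuromechanical simulation of Caenorhabditis elegans forward
    crawling driven by a chain of network (non-pacemaker) rhythmic pattern
    generators in the ventral nerve cord. Implements the repeating seven-class
    motorneuron circuit as a continuous-time recurrent neural network with
    chemical synapses and gap junctions, a 2D rod-and-spring body in a
    linear-drag agar environment, leaky-integrator muscles with Hill-type
    force-length and force-velocity properties, the two-stage evolutionary
    search over the 44-parameter genotype, and the behavioral analysis suite
    (kymographs, kinematic filters, paralysis and gap-junction overexpression
    experiments, subcircuit oscillation scores, interunit necessity and
    sufficiency, entrainment and phase-shift analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
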