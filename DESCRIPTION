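Package: eiassembly
Title: Homeostatic Formation of Excitatory-Inhibitory Assemblies in Rate Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a recurrent rate network of pyramidal (Pyr) neurons and
    parvalbumin-expressing (PV) interneurons with Wilson-Cowan dynamics and
    stimulus-tuned external input on a periodic three-dimensional stimulus
    grid. Homeostatic plasticity rules acting on both the excitatory input
    and the inhibitory output synapses of the interneurons drive the
    formation of excitatory-inhibitory assemblies. The package provides the
    network constructor, steady-state solver, local and gradient-based
    plasticity rules with sign-constraint reparameterisation and Adam,
    virtual knock-out experiments, single-neuron perturbation analysis, and
    the quantitative measures (response similarity, stimulus selectivity,
    update angles, synapse-sampling significance analysis, receptive-field
    correlation statistics, and a Mann-Whitney U test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
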