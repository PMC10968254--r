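Package: endogame
Title: Evolutionary Dynamics of an Endosymbiosis Signaling Game
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based simulation of an information-asymmetric
    sender-receiver signaling game between proto-mitochondria (senders)
    and proto-eukaryotes (receivers) that may fuse into cellularized
    endo-pairs with a shared inclusive utility.  Populations evolve by
    reward-proportional Dirichlet-multinomial resampling with mutation
    and spatial dispersion.  Includes per-compartment outcome tracking,
    signaling-equilibrium classification (separating, pooling,
    babbling), Pareto analysis of the payoff table, and analytic
    predictions for the stationary cellularized fraction under the
    fusion/fission queueing process.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
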