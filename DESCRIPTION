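Package: rescuesim
Title: Stochastic Lattice Simulation of Tumor Growth and Cooperative
    Apoptosis Rescue Protocols
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulator of a three-dimensional society of normal
    and tumor cells on a bounded lattice. Cells follow stochastic life
    protocols (proliferation under contact inhibition, generation potential,
    intrinsic apoptosis, mutation with repair-first ordering), and two
    inter-cellular rescue protocols -- "please die" signals emitted by
    spatially violated normal cells and "I'm dying" death reports emitted by
    protocol-killed cells -- act through per-cell signal accumulators and
    two-threshold responses to selectively eradicate tumors. Includes
    replicated sweep experiments over proliferation ratios, signal parameter
    sets, stochastic resistance levels, and delayed activation volumes, with
    Wilson-interval success-rate summaries, plus a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
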