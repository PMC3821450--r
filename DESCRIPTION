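Package: phenostream
Title: Consensus Segmentation, Category Attribution and Stream Models for
    Phenomenological Texts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of phenomenological texts
    (first-person verbal reports of ongoing conscious experience) coded by
    panels of human judges. Computes per-boundary inter-observer agreement
    indices from judge segmentation marks and derives consensus segments by
    a mean-threshold rule; builds proportion matrices of mental-category
    attributions per segment and flags significantly high or low cells with
    one-sided exact binomial tests; represents a coded stream of
    consciousness as a Petri-net-style dynamic model with content places,
    intra-segment binding, causal arcs and micro-episodes, exported to DOT
    and PNML; and simulates judge panels to calibrate agreement thresholds
    and the flagging test. Ships reconstructions of two classical
    annotation datasets: a journal excerpt segmented and coded by a
    sixteen-judge panel, and a thirty-sentence interior-monolog excerpt
    coded into four content lanes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
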