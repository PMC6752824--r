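Package: regomax
Title: Reduced Google Matrix Analysis of Directed Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Google matrix construction, PageRank and CheiRank ranking, and the
    reduced Google matrix (REGOMAX) decomposition for directed networks.  The
    reduced Google matrix of a node subset captures all direct and indirect
    pathways through the surrounding network and splits into direct (Grr),
    PageRank-projector (Gpr) and indirect (Gqr) components, from which hidden
    links, PageRank sensitivities to link perturbations, and iteratively grown
    "friend" interaction networks are derived.  Ships transcriptions of
    published cancer, drug and epidemiological ranking tables together with
    top-j ranked-list overlap statistics, and a synthetic directed-network
    generator (heavy-tailed preferential attachment, hubs, stratified node
    groups, planted indirect pathways) so the whole pipeline is testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
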