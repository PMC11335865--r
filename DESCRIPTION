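Package: sociomix
Title: Homophily, Degree-Preserving Null Models, and Tie Reciprocity in
    Directed Social Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing attribute-based homophily in directed
    online social networks. Parses node-attribute tables and edge lists
    (including the tab-separated Pokec snapshot dialect), applies
    plausibility filters to self-reported age, height, and body mass,
    computes Newman's numeric assortativity coefficient on directed graphs
    (plain and conditioned on intervals of a second trait), tests observed
    assortativity against a degree-class attribute-shuffle null ensemble,
    builds long-format follower-followee dyad tables, fits random-intercept
    trait-similarity and tie-reciprocity mixed models with per-gender
    simple slopes and predicted-probability contrasts, and generates
    synthetic networks with known homophily and reciprocation structure
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
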