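Package: cyclostab
Title: Steady-State Stability of Reaction Networks from Their Influence Topology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Local steady-state stability analysis of autonomous ODE reaction
    networks from their signed directed bipartite influence topology (the
    directed species-reaction graph). Enumerates bipartite cycles, assembles
    the principal minors of the community/transition matrix as signed sums of
    non-overlapping cycle products (a bipartite form of Sachs' theorem),
    computes Hurwitz determinants and Routh unstable-root counts exactly in a
    built-in rational multivariate polynomial ring, reduces parameters by
    stoichiometric scaling, cycle compaction and temporal scaling, maps the
    stability phase space over the reduced parameters with Hopf-candidate
    zones, and partitions general networks into upstream/downstream levels of
    strongly connected components. Ships the classical fixture networks
    (Jenkin-Maxwell governor, van der Pol, Lotka-Volterra, Brusselator,
    Sel'kov, Repressilator, single n-cycles) with their steady-state mappings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
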