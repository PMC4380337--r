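upstream_decay_topology <- function() {
  # x3 decays autonomously upstream; x1/x2 form a predator-prey pair whose
  # interaction reaction is modulated by x3
  build_topology(list(
    v1 = list(inputs = c(x1 = "+"), outputs = c(x1 = "+1")),
    v2 = list(inputs = c(x1 = "+", x2 = "+", x3 = "+"),
              outputs = c(x1 = "-1", x2 = "+1")),
    v3 = list(inputs = c(x2 = "+"), outputs = c(x2 = "-1")),
    v4 = list(inputs = c(x3 = "+"), outputs = c(x3 = "-1"))
  ), species = c("x1", "x2", "x3"))
}

driven_decay_topology <- function() {
  # levels swapped: the predator-prey pair drives x3 from upstream
  build_topology(list(
    v1 = list(inputs = c(x1 = "+"), outputs = c(x1 = "+1")),
    v2 = list(inputs = c(x1 = "+", x2 = "+"),
              outputs = c(x1 = "-1", x2 = "+1", x3 = "+1")),
    v3 = list(inputs = c(x2 = "+"), outputs = c(x2 = "-1")),
    v4 = list(inputs = c(x3 = "+"), outputs = c(x3 = "-1"))
  ), species = c("x1", "x2", "x3"))
}

test_that("special nodes are classified by the four definitions", {
  nc <- classify_special_nodes(jm_topology())
  expect_equal(nc$orphan_reactions, "v0")
  expect_length(nc$childless_species, 0)
  expect_length(nc$childless_reactions, 0)

  rp <- classify_special_nodes(make_classical_network("repressilator")$topology)
  expect_length(unlist(rp), 0)

  # a species receiving output but feeding nothing is childless
  topo <- build_topology(list(
    v1 = list(inputs = c(x1 = "+"), outputs = c(x1 = "-1", x2 = "+1"))
  ), species = c("x1", "x2"))
  expect_equal(classify_special_nodes(topo)$childless_species, "x2")

  # clamped species are forced into the orphan class
  topo2 <- build_topology(list(
    v1 = list(inputs = c(x1 = "+", x2 = "+"), outputs = c(x1 = "-1", x2 = "-1"))
  ), species = c("x1", "x2"), clamped = "x2")
  expect_true("x2" %in% classify_special_nodes(topo2)$orphan_species)
})

test_that("two-level networks decompose upstream-first", {
  dA <- level_decomposition(upstream_decay_topology())
  expect_equal(nrow(dA$levels), 2)
  expect_equal(dA$levels$species[[1]], "x3")
  expect_equal(dA$levels$species[[2]], c("x1", "x2"))
  expect_equal(dA$levels$verdict[1], "stable")
  expect_match(dA$levels$verdict[2], "parameter-dependent")

  dC <- level_decomposition(driven_decay_topology())
  expect_equal(dC$levels$species[[1]], c("x1", "x2"))
  expect_equal(dC$levels$species[[2]], "x3")
  expect_match(dC$levels$verdict[2], "non-autonomous")

  # any single-SCC fixture is one level
  dJ <- level_decomposition(jm_topology())
  expect_equal(nrow(dJ$levels), 1)
  expect_equal(dJ$levels$species[[1]], c("x1", "x2", "x3"))
})

test_that("the downstream level of the modulated pair is the predator-prey topology", {
  dA <- level_decomposition(upstream_decay_topology())
  sub <- dA$levels$topology[[2]]
  lv <- make_classical_network("lotka_volterra")$topology
  to_colored_graph <- function(topo) {
    g <- cyclostab:::topo_igraph(topo)
    vk <- ifelse(startsWith(igraph::V(g)$name, "x|"), 1L, 2L)
    el <- igraph::as_edgelist(g)
    esgn <- integer(nrow(el))
    for (i in seq_len(nrow(el))) {
      if (startsWith(el[i, 1], "x|")) {
        esgn[i] <- topo$jac$sign[topo$jac$species == substring(el[i, 1], 3) &
                                   topo$jac$reaction == substring(el[i, 2], 3)]
      } else {
        esgn[i] <- topo$stoich$sign[
          topo$stoich$reaction == substring(el[i, 1], 3) &
            topo$stoich$species == substring(el[i, 2], 3)]
      }
    }
    list(g = g, vcol = vk, ecol = as.integer(esgn + 2))
  }
  a <- to_colored_graph(sub); b <- to_colored_graph(lv)
  expect_true(igraph::isomorphic(a$g, b$g, method = "vf2",
                                 vertex.color1 = a$vcol, vertex.color2 = b$vcol,
                                 edge.color1 = a$ecol, edge.color2 = b$ecol))
})

test_that("level reports serialize", {
  dA <- level_decomposition(upstream_decay_topology())
  tab <- level_report(dA)
  expect_equal(nrow(tab), 2)
  pj <- tempfile(fileext = ".json")
  level_report(dA, path = pj)
  expect_true(file.exists(pj))
})

test_that("n-cycles canonicalize to all arrows or a single blunt arrow", {
  for (n in c(2, 3, 4)) {
    pos <- canonical_sign_form(make_ncycle(n, 1)$topology)
    expect_equal(pos$sign_string, strrep("0", 2 * n))
    neg <- canonical_sign_form(make_ncycle(n, -1)$topology)
    expect_equal(sum(strsplit(neg$sign_string, "")[[1]] == "1"), 1)
  }
  # a canonical topology maps to itself
  cf <- canonical_sign_form(make_ncycle(3, 1)$topology)
  again <- canonical_sign_form(cf$topology)
  expect_length(again$negated_nodes, 0)
  expect_identical(again$sign_string, cf$sign_string)
})

test_that("node negation preserves every minor and the canonical form", {
  for (seed in 1:12) {
    topo <- random_topology(2, 2, seed + 900)
    base_minors <- principal_minors(topo)
    cf0 <- canonical_sign_form(topo)
    nodes <- c(topo$species$id, topo$reactions$id)
    kinds <- c(rep("species", nrow(topo$species)),
               rep("reaction", nrow(topo$reactions)))
    # single-node negation: symbolically identical minors
    i <- (seed %% length(nodes)) + 1
    t1 <- cyclostab:::negate_node(topo, nodes[i], kinds[i])
    m1 <- principal_minors(t1)
    for (q in 0:base_minors$n)
      expect_true(p_eq_(base_minors$b[[q + 1]], m1$b[[q + 1]]),
                  info = paste("seed", seed, "q", q))
    # random subsets: identical canonical representative
    set.seed(seed)
    for (rep in 1:4) {
      t2 <- topo
      for (j in which(stats::runif(length(nodes)) < 0.5))
        t2 <- cyclostab:::negate_node(t2, nodes[j], kinds[j])
      cf2 <- canonical_sign_form(t2)
      expect_identical(cf2$sign_string, cf0$sign_string,
                       info = paste("seed", seed, "rep", rep))
    }
  }
})
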