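test_that("governor network builds with the expected counts and flags", {
  topo <- jm_topology()
  g <- glance(topo)
  expect_equal(g$n_species, 3)
  expect_equal(g$n_reactions, 3)
  expect_equal(g$n_orphan_reactions, 1)
  expect_equal(g$S, 5)
  expect_equal(g$J, 3)
  expect_equal(g$n_unknown_signs, 0)
})

test_that("degenerate and malformed network descriptions error", {
  expect_error(build_topology(list()), "at least one reaction")
  expect_error(build_topology(list(
    v1 = list(inputs = c(x9 = "+"), outputs = c(x1 = "+1"))
  ), species = "x1"), "missing species")
  expect_error(build_topology(list(
    v1 = list(inputs = c(x1 = "+"), outputs = character(0))
  ), species = "x1"), "no stoichiometric outputs")
  expect_error(build_topology(list(
    v1 = list(inputs = c(x1 = "+"), outputs = c(x1 = "+1")),
    v1 = list(inputs = c(x1 = "+"), outputs = c(x1 = "-1"))
  )), "duplicate reaction")
})

test_that("unknown signs expand to fixed-sign topologies in lexicographic order", {
  topo <- build_topology(list(
    v1 = list(inputs = c(x1 = "?"), outputs = c(x1 = "-1", x2 = "?1")),
    v2 = list(inputs = c(x2 = "+"), outputs = c(x1 = "+1"))
  ), species = c("x1", "x2"))
  expect_equal(glance(topo)$n_unknown_signs, 2)
  ex <- expand_sign_assignments(topo)
  expect_length(ex, 4)
  # all fixed-sign, deduplicated sign patterns, first assignment all '+'
  pats <- vapply(ex, function(t) paste(c(t$jac$sign, t$stoich$sign),
                                       collapse = ","), character(1))
  expect_equal(anyDuplicated(pats), 0)
  # the formerly unknown edges are all '+' in the first assignment
  first <- ex[[1]]
  expect_equal(first$jac$sign[is.na(topo$jac$sign)],
               rep(1L, sum(is.na(topo$jac$sign))))
  expect_equal(first$stoich$sign[is.na(topo$stoich$sign)],
               rep(1L, sum(is.na(topo$stoich$sign))))
  # u = 0 returns the input alone
  expect_length(expand_sign_assignments(ex[[1]]), 1)
})

test_that("a fully unknown-sign 3-cycle expands to 8 topologies", {
  topo <- build_topology(list(
    va = list(inputs = c(x1 = "+"), outputs = c(x2 = "?1")),
    vb = list(inputs = c(x2 = "+"), outputs = c(x3 = "?1")),
    vc = list(inputs = c(x3 = "+"), outputs = c(x1 = "?1"))
  ), species = c("x1", "x2", "x3"))
  expect_length(expand_sign_assignments(topo), 8)
})

test_that("rotation network transition matrix matches the analytic form", {
  topo <- build_topology(list(
    v1 = list(inputs = c(x2 = "+1"), outputs = c(x1 = "-1")),
    v2 = list(inputs = c(x1 = "+1"), outputs = c(x2 = "+1"))
  ), species = c("x1", "x2"))
  H <- assemble_transition_matrix(topo)
  expect_equal(unname(H), matrix(c(0, -1, 1, 0), 2, 2))
})

test_that("assembled H equals a finite-difference Jacobian of the rate laws", {
  for (nm in c("jenkin_maxwell", "van_der_pol", "lotka_volterra",
               "brusselator", "selkov")) {
    fx <- make_classical_network(nm)
    cs <- fx$constants
    xs <- fx$steady_state(cs)
    H <- assemble_transition_matrix(fx$topology, fx$jac_values(cs))
    Hfd <- fd_transition(function(x) fx$rate_laws(x, cs), xs)
    expect_equal(unname(H), Hfd, tolerance = 1e-6, info = nm)
  }
})

test_that("H equals the product of the Jacobian and stoichiometry matrices", {
  for (seed in 1:5) {
    topo <- random_topology(4, 4, seed)
    Hp <- cyclostab:::transition_matrix_poly(topo)
    # direct double summation of Eq-style products
    sp <- topo$species$id
    H2 <- matrix(0, length(sp), length(sp))
    for (i in seq_along(sp)) for (j in seq_along(sp)) {
      tot <- 0
      for (k in seq_len(nrow(topo$reactions))) {
        rid <- topo$reactions$id[k]
        je <- topo$jac[topo$jac$reaction == rid & topo$jac$species == sp[i], ]
        se <- topo$stoich[topo$stoich$reaction == rid &
                            topo$stoich$species == sp[j], ]
        if (nrow(je) == 1 && nrow(se) == 1)
          tot <- tot + (je$sign * je$w_num / je$w_den) *
            (se$sign * se$w_num / se$w_den)
      }
      H2[i, j] <- tot
    }
    Hnum <- matrix(vapply(Hp, p_num_, numeric(1)), nrow(Hp), ncol(Hp))
    expect_equal(Hnum, H2, tolerance = 1e-12)
  }
})

test_that("serialization round trips byte-stably and rejects bad documents", {
  for (nm in fixture_names) {
    topo <- make_classical_network(nm)$topology
    txt <- write_topology(topo)
    back <- read_topology(txt)
    expect_identical(write_topology(back), txt, info = nm)
  }
  expect_error(read_topology('{"schema": "influence-topology/1", "species": []}'),
               "missing 'reactions'")
  expect_error(read_topology('{"schema": "other/9", "species": [], "reactions": []}'),
               "unknown schema")
  expect_error(read_topology("{not json"), "malformed")
})

test_that("DOT export carries all nodes and signed edges", {
  topo <- make_classical_network("repressilator")$topology
  dot <- topology_to_dot(topo)
  lines <- strsplit(dot, "\n")[[1]]
  expect_equal(sum(grepl("shape=ellipse", lines)), 3)
  expect_equal(sum(grepl("shape=box", lines)), 6)
  expect_equal(sum(grepl("->", lines, fixed = TRUE)), 12)
  # 3 repression inputs + 3 decay outputs carry blunt arrowheads
  expect_equal(sum(grepl("arrowhead=tee", lines)), 6)
})
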