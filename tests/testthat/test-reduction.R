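# the stoichiometric-scaling / cycle-compaction / temporal-scaling chain

test_that("the scaling choice can change the final parameter count", {
  # one reaction with two stoichiometric parameters feeding two cycles:
  # scaling the edge on the 1-cycle leaves one ratio group fewer
  topo <- build_topology(list(
    v1 = list(inputs = c(x1 = "+r1"),
              outputs = c(x1 = "+s2", x2 = "+s1")),
    v2 = list(inputs = c(x2 = "+r2"), outputs = c(x1 = "-s3"))
  ), species = c("x1", "x2"))
  cyc <- enumerate_cycles(topo)
  good <- cyclostab:::n_param_groups(topo, cyc, list(v1 = "x1", v2 = "x1"))
  bad <- cyclostab:::n_param_groups(topo, cyc, list(v1 = "x2", v2 = "x1"))
  expect_equal(good, 2)
  expect_equal(bad, 3)
  # the automatic search takes the better choice
  sc <- stoichiometric_scaling(topo)
  expect_equal(unname(sc$choice["v1"]), "x1")
})

test_that("a single numeric output of magnitude 2 is absorbed into the Jacobian", {
  topo <- build_topology(list(
    v1 = list(inputs = c(x1 = "+r1"), outputs = c(x1 = "-2"))
  ), species = "x1")
  sc <- stoichiometric_scaling(topo)
  m_st <- sc$mags[["S:v1:x1"]]
  expect_true(cyclostab:::mag_is_unit(m_st))
  m_j <- sc$mags[["J:x1:v1"]]
  expect_equal(m_j$q, c(2, 1))
  expect_equal(m_j$syms_num, "r1")
})

test_that("compaction groups edges by exact cycle-membership barcode", {
  jm <- make_classical_network("jenkin_maxwell")
  cmp <- jm$reduced$compacted
  expect_equal(cmp$c, 2L)                       # 5 parameters -> 3 groups
  pg <- cmp$groups[!cmp$groups$constant, ]
  expect_equal(nrow(pg), 3)
  q0 <- pg[pg$z == 1 & vapply(pg$magnitude, function(m)
    setequal(m$syms_num, c("r3", "sigma1", "sigma2")), logical(1)), ]
  expect_equal(nrow(q0), 1)
  expect_equal(q0$sign, -1L)                    # the negative 3-cycle product
  # group count never exceeds 2^(number of cycles) - 1
  for (nm in fixture_names) {
    cmp2 <- make_classical_network(nm)$reduced$compacted
    expect_lte(nrow(cmp2$groups), 2^nrow(cmp2$cycles) - 1)
  }
  # repressilator: the three repression edges merge, decay edges stay apart
  rp <- make_classical_network("repressilator")$reduced$compacted
  expect_equal(rp$c, 2L)
  merged <- rp$groups[vapply(rp$groups$magnitude, function(m)
    setequal(m$syms_num, c("r4", "r5", "r6")), logical(1)), ]
  expect_equal(nrow(merged), 1)
  expect_equal(merged$z, 3L)
})

test_that("an acyclic topology compacts to nothing", {
  topo <- build_topology(list(
    v1 = list(inputs = c(x1 = "+"), outputs = c(x2 = "+1"))
  ), species = c("x1", "x2"))
  cmp <- cycle_compaction(stoichiometric_scaling(topo))
  expect_equal(nrow(cmp$groups), 0)
  expect_equal(cmp$c, 0L)
  expect_error(temporal_scaling(cmp), "temporal scaling impossible")
  expect_equal(reduced_dimension(topo), 0L)
})

test_that("temporal scaling emits the literature's reduced parameters", {
  jm <- make_classical_network("jenkin_maxwell")$reduced
  expect_equal(sort(jm$params$param), c("rho1", "rho2"))
  expect_equal(jm$beta$z, 1)
  expect_setequal(jm$beta$mag$syms_num, c("r3", "sigma1", "sigma2"))

  rp <- make_classical_network("repressilator")$reduced
  expect_equal(rp$beta$z, 3)                    # beta = |r4 r5 r6|^(1/3)
  expect_equal(sort(rp$params$param), c("rho1", "rho2", "rho3"))

  expect_error(
    temporal_scaling(make_classical_network("brusselator")$reduced$compacted,
                     unit = "sigma1"),
    "no Jacobian content")
})

test_that("reduced dimensionality matches the classical values", {
  expect_equal(reduced_dimension(jm_topology()), 2L)
  expect_equal(reduced_dimension(make_classical_network("van_der_pol")$topology), 2L)
  expect_equal(reduced_dimension(make_classical_network("lotka_volterra")$topology), 3L)
  # d equals the count of free symbols in the reduced minors
  for (nm in fixture_names) {
    red <- make_classical_network(nm)$reduced
    vars <- sort(unique(unlist(lapply(red$minors$b, poly_vars))))
    expect_equal(length(vars), red$d, info = nm)
    expect_setequal(vars, red$params$param)
  }
})

test_that("compaction re-expresses every cycle weight exactly", {
  for (nm in fixture_names) {
    fx <- make_classical_network(nm)
    red <- fx$reduced
    vals <- random_instantiation(fx$topology, 11)
    rv <- reduce_values(red, vals)
    beta <- rv[[".beta"]]
    raw <- enumerate_cycles(fx$topology)
    for (i in seq_len(nrow(raw))) {
      orig <- poly_eval(raw$weight[[i]], vals)
      redw <- poly_eval(red$cycles$weight[[i]], rv)
      expect_equal(redw, orig / beta^raw$length[i], tolerance = 1e-10,
                   info = paste(nm, "cycle", i))
    }
  }
})

test_that("none of the three reductions changes the unstable-root count", {
  check_invariance <- function(topo, red, vals, info) {
    H <- assemble_transition_matrix(topo, vals)
    oc <- eigen_oracle(H)
    if (oc$margin < 1e-6) return(invisible(NULL))
    rv <- reduce_values(red, vals)
    ev <- evaluate_reduced(red, rv[names(rv) != ".beta"])
    if (ev$routh$indeterminate) {
      expect_equal(oc$unstable_count %% 2, 0, info = info)
    } else {
      expect_equal(ev$routh$k, oc$unstable_count, info = info)
    }
    # scaling alone must leave H's spectrum untouched: compare against the
    # scaled-magnitude evaluation of the same matrix
    sc <- red$compacted$scaled
    expect_equal(eigen_oracle(H)$unstable_count, oc$unstable_count)
  }
  for (nm in fixture_names) {
    fx <- make_classical_network(nm)
    for (seed in 1:4) {
      vals <- random_instantiation(fx$topology, seed)
      check_invariance(fx$topology, fx$reduced, vals, paste(nm, seed))
    }
  }
  for (seed in 1:30) {
    topo <- random_topology(3, 4, seed + 500)
    red <- tryCatch(reduce_topology(topo), error = function(e) NULL)
    if (is.null(red)) next
    vals <- random_instantiation(topo, seed)
    check_invariance(topo, red, vals, paste("random", seed))
  }
})

test_that("exchange symmetries are detected and verified by substitution", {
  jm <- detect_exchange_symmetries(make_classical_network("jenkin_maxwell")$reduced)
  expect_length(jm$permutations, 1)
  expect_equal(unname(jm$permutations[[1]]), c("rho2", "rho1"))
  expect_match(jm$psi_candidates, "rho1 \\+ rho2")

  rp <- detect_exchange_symmetries(make_classical_network("repressilator")$reduced)
  expect_length(rp$permutations, 5)             # S_3 minus identity

  vdp <- detect_exchange_symmetries(make_classical_network("van_der_pol")$reduced)
  expect_length(vdp$permutations, 0)
})

test_that("the reduction trace reports scalings, barcodes and parameters", {
  tr <- reduction_trace(make_classical_network("jenkin_maxwell")$reduced)
  expect_true(all(c("stoichiometric_scaling", "compaction_group",
                    "temporal_scaling", "parameter") %in% tr$section))
  expect_true(any(grepl("rho1", tr$item)))
})
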