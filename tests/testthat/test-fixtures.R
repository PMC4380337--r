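test_that("pipeline-computed expressions match the published reduced forms", {
  for (nm in c(fixture_names, "repressilator_positive")) {
    fx <- make_classical_network(nm)
    differ <- fx$expected$expected_to_differ
    if (is.null(differ)) differ <- character(0)
    for (bq in names(fx$expected$minors)) {
      q <- as.integer(sub("b", "", bq))
      same <- p_eq_(fx$reduced$minors$b[[q + 1]],
                    poly_parse(fx$expected$minors[[bq]]))
      if (bq %in% differ) {
        expect_false(same, info = paste(nm, bq, "flagged discrepancy"))
      } else {
        expect_true(same, info = paste(nm, bq))
      }
    }
    for (dq in names(fx$expected$deltas)) {
      q <- as.integer(sub("d", "", dq))
      expect_true(p_eq_(fx$reduced$hurwitz$deltas[[q]],
                        poly_parse(fx$expected$deltas[[dq]])),
                  info = paste(nm, dq))
    }
  }
})

test_that("the flagged Sel'kov minor differs only in the sigma2 term sign", {
  fx <- make_classical_network("selkov")
  published <- poly_parse(fx$expected$minors[["b2"]])
  computed <- fx$reduced$minors$b[[3]]
  diff <- computed - published
  expect_true(p_eq_(diff, poly_parse("2*sigma2*rho1*rho3")))
})

test_that("unknown fixture names and bad constants error", {
  expect_error(make_classical_network("lorenz"), "unknown fixture")
  expect_error(make_classical_network("brusselator", list(k2 = 1, a = 3)),
               "k2 > a")
  expect_error(make_classical_network("lotka_volterra", list(k1 = -1)),
               "positive")
})

test_that("n-cycle closed forms agree with the Routh route (odd n <= 9, both signs)", {
  for (n in seq(1, 9, by = 2)) for (s in c(1, -1)) {
    fx <- make_ncycle(n, s)
    dl <- vapply(fx$reduced$hurwitz$deltas, p_num_, numeric(1))
    expect_equal(dl, fx$expected$deltas_num, info = paste("n", n, "sign", s))
    rc <- count_unstable_roots(fx$reduced$hurwitz)
    expect_equal(rc$k, fx$expected$k, info = paste("n", n, "sign", s))
    # and with the eigenvalue oracle at unit weights
    vals <- stats::setNames(rep(1, n), sprintf("c%02d", 1:n))
    oc <- eigen_oracle(assemble_transition_matrix(fx$topology, vals))
    expect_equal(oc$unstable_count, fx$expected$k)
  }
})

test_that("even cycles carry no first-order information", {
  for (n in c(2, 4)) {
    fx <- make_ncycle(n, 1)
    expect_true(all(vapply(fx$reduced$hurwitz$deltas, poly_is_zero, logical(1))))
    expect_true(count_unstable_roots(fx$reduced$hurwitz)$indeterminate)
  }
})

test_that("steady states project into the zones the closed forms predict", {
  lv <- make_classical_network("lotka_volterra")
  pt <- function(s1) {
    v <- map_steady_state("lotka_volterra", list(s1 = s1))
    evaluate_reduced(lv$reduced, stats::setNames(v$value, v$param))
  }
  expect_equal(pt(2)$routh$k, 2)           # oscillatory divergence
  expect_equal(pt(0.5)$routh$k, 0)         # oscillatory convergence
  expect_true(pt(1)$routh$indeterminate)   # the neutral center

  # Brusselator in the classical instability region B > 1 + A^2
  br <- make_classical_network("brusselator", list(k0 = 1, k1 = 1, k2 = 5, a = 1))
  v <- map_steady_state(br)
  ev <- evaluate_reduced(br$reduced, stats::setNames(v$value, v$param))
  expect_equal(ev$routh$k, 2)
  # and stable outside it
  br2 <- make_classical_network("brusselator", list(k0 = 2, k1 = 1, k2 = 3, a = 1))
  v2 <- map_steady_state(br2)
  ev2 <- evaluate_reduced(br2$reduced, stats::setNames(v2$value, v2$param))
  expect_equal(ev2$routh$k, 0)
})

test_that("the eigen oracle reports spectra, counts and margins", {
  oc <- eigen_oracle(diag(c(-1, -2)))
  expect_equal(oc$unstable_count, 0)
  expect_equal(oc$margin, 1)
  # unit 3-cycle pattern: eigenvalues are the cube roots of unity
  M <- matrix(c(0, 0, 1, 1, 0, 0, 0, 1, 0), 3, 3)
  oc3 <- eigen_oracle(M)
  expect_equal(oc3$unstable_count, 1)
  expect_equal(sort(Re(oc3$eigenvalues)), c(-0.5, -0.5, 1), tolerance = 1e-10)
  expect_error(eigen_oracle(matrix(c(1, NaN, 0, 1), 2, 2)), "non-finite")
})

test_that("random instantiation is reproducible, positive and seed-sensitive", {
  topo <- jm_topology()
  v1 <- random_instantiation(topo, 5)
  v2 <- random_instantiation(topo, 5)
  expect_identical(v1, v2)
  expect_true(all(v1 >= 0.1 & v1 <= 10))
  others <- vapply(1:10, function(s)
    !identical(random_instantiation(topo, s + 10), v1), logical(1))
  expect_true(all(others))
})

test_that("level-demo trajectories behave as the decomposition predicts", {
  # upstream decay, downstream predator-prey: x3 dies out, x1/x2 oscillate
  fA <- function(x) c(
    x[1] - (1 + x[3]) * x[1] * x[2],
    (1 + x[3]) * x[1] * x[2] - x[2],
    -0.1 * x[3])
  trA <- simulate_trajectories(fA, c(x1 = 1, x2 = 3, x3 = 1),
                               horizon = 100, step = 0.01)
  expect_false(attr(trA, "diverged"))
  expect_lt(trA$x3[nrow(trA)], 1e-3)
  late1 <- trA$x1[trA$time > 50]
  expect_true(any(diff(late1) > 0) && any(diff(late1) < 0))  # oscillatory
  expect_lt(max(trA$x1), 1e3)

  # upstream predator-prey driving a downstream decay: x3 keeps oscillating
  fC <- function(x) c(
    x[1] - x[1] * x[2],
    x[1] * x[2] - x[2],
    x[1] * x[2] - 0.1 * x[3])
  trC <- simulate_trajectories(fC, c(x1 = 1, x2 = 3, x3 = 1),
                               horizon = 100, step = 0.01)
  late3 <- trC$x3[trC$time > 50]
  expect_true(any(diff(late3) > 0) && any(diff(late3) < 0))

  # zero state under pure linear decay stays identically zero
  tr0 <- simulate_trajectories(function(x) -x, c(x1 = 0, x2 = 0),
                               horizon = 1, step = 0.01)
  expect_true(all(tr0$x1 == 0) && all(tr0$x2 == 0))

  # divergence is flagged
  trD <- simulate_trajectories(function(x) 10 * x, c(x1 = 1),
                               horizon = 10, step = 0.01)
  expect_true(attr(trD, "diverged"))
})
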