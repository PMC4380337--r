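test_that("charpoly coefficients alternate the minor signs", {
  # decay 1-cycle: b = (1, -1) -> a = (1, 1)
  a <- charpoly_coefficients(list(poly_const(1), poly_const(-1)))
  expect_equal(vapply(a, p_num_, numeric(1)), c(1, 1))
  expect_error(charpoly_coefficients(list(poly_const(2))), "b_0")
})

test_that("coefficients from minors match the expanded characteristic polynomial", {
  for (seed in 1:10) {
    topo <- random_topology(4, 4, seed + 7)
    H <- assemble_transition_matrix(topo)
    b <- minors_numeric(H)
    a <- (-1)^(0:4) * b
    # oracle: expand prod(lambda - lambda_i) from the spectrum
    lam <- eigen(H, only.values = TRUE)$values
    co <- c(1 + 0i)
    for (l in lam) co <- c(co, 0) - c(0, co) * l
    expect_equal(a, Re(co), tolerance = 1e-8)
  }
})

test_that("symbolic Hurwitz determinants reproduce the governor results", {
  red <- make_classical_network("jenkin_maxwell")$reduced
  hw <- red$hurwitz
  expect_true(p_eq_(hw$deltas[[2]],
                    poly_parse("rho1*rho2*(rho1 + rho2 - 1)")))
  # the single destabilising multiplicative topology of Delta_2 is the
  # 3-cycle product c_0 * c_3 = -rho1*rho2
  nt <- hw$negative_terms[[2]]
  expect_equal(nrow(nt), 1)
  expect_equal(nt$term, "rho1*rho2")
  nt3 <- hw$negative_terms[[3]]
  expect_equal(nt3$term, "rho1^2*rho2^2")
})

test_that("n = 1 gives Delta_1 = a_1 and the template route matches throughout", {
  one <- hurwitz_determinants(list(poly_const(1), poly_sym("a1")))
  expect_true(p_eq_(one$deltas[[1]], poly_sym("a1")))
  for (nm in c("jenkin_maxwell", "van_der_pol", "lotka_volterra",
               "brusselator", "selkov", "repressilator")) {
    red <- make_classical_network(nm)$reduced
    tmpl <- hurwitz_from_cycles(red$minors)
    det_route <- red$hurwitz
    for (q in seq_along(det_route$deltas)) {
      expect_true(p_eq_(tmpl$deltas[[q]], det_route$deltas[[q]]),
                  info = paste(nm, "Delta", q))
    }
  }
  # all-zero minors give all-zero determinants
  z <- hurwitz_from_cycles(structure(
    list(b = list(poly_const(1), poly_const(0), poly_const(0)),
         combos = list(), n = 2, cycles = NULL), class = "minor_set"))
  expect_true(all(vapply(z$deltas, poly_is_zero, logical(1))))
})

test_that("Delta_n = a_n * Delta_{n-1} holds symbolically on all fixtures", {
  for (nm in fixture_names) {
    red <- make_classical_network(nm)$reduced
    n <- red$minors$n
    if (n < 2) next
    a_n <- charpoly_coefficients(red$minors$b)[[n + 1]]
    expect_true(p_eq_(red$hurwitz$deltas[[n]],
                      a_n * red$hurwitz$deltas[[n - 1]]), info = nm)
  }
})

test_that("sign-change counting handles plain and degenerate sequences", {
  expect_equal(count_unstable_roots(c(1, -1, -1))$k, 2)    # array (+,+,-,+)
  expect_equal(count_unstable_roots(c(1, 1, -1))$k, 1)     # (+,+,+,-)
  expect_equal(count_unstable_roots(c(2, 5, 0.3))$k, 0)
  # leading zero string of the positive 3-cycle: (a0, 0, +, -) -> k = 1
  rc <- count_unstable_roots(c(0, 1, -1))
  expect_equal(rc$k, 1)
  expect_equal(rc$zero_strings$start, 1L)
  # trailing zero string truncates
  rc2 <- count_unstable_roots(c(1, 2, 0))
  expect_equal(rc2$k, 0)
  expect_true(rc2$truncated)
  # every determinant zero: no first-order information
  rc3 <- count_unstable_roots(c(0, 0))
  expect_true(rc3$indeterminate)
  expect_true(is.na(rc3$k))
  expect_error(count_unstable_roots(c(1, NaN, 1)), "non-finite")
})

test_that("Routh count equals the eigenvalue count away from boundaries", {
  set.seed(42)
  tried <- 0
  for (rep in 1:200) {
    n <- sample(2:6, 1)
    M <- matrix(stats::rnorm(n * n), n, n)
    oc <- eigen_oracle(M)
    if (oc$margin < 1e-6) next
    b <- minors_numeric(M)
    a <- (-1)^(0:n) * b
    d <- hurwitz_numeric(a)
    if (any(abs(d) < 1e-9 * (1 + cummax(abs(d))))) next
    tried <- tried + 1
    expect_equal(count_unstable_roots(d)$k, oc$unstable_count,
                 info = paste("rep", rep))
    # stability iff all determinants positive
    expect_equal(all(d > 0), oc$unstable_count == 0)
  }
  expect_gt(tried, 150)
})

test_that("Orlando products agree with the determinant route", {
  # purely imaginary pair: both final determinants vanish
  oc <- orlando_check(c(1i, -1i))
  expect_equal(unname(oc), c(0, 0))
  expect_equal(unname(orlando_check(-1)["delta_last"]), 1)
  set.seed(7)
  for (rep in 1:20) {
    nr <- sample(1:2, 1)          # real roots
    nc <- sample(0:2, 1)          # conjugate pairs
    lam <- c(-stats::runif(nr, 0.2, 2),
             unlist(lapply(seq_len(nc), function(i) {
               re <- -stats::runif(1, 0.2, 2); im <- stats::runif(1, 0.2, 2)
               c(complex(real = re, imaginary = im),
                 complex(real = re, imaginary = -im))
             })))
    n <- length(lam)
    if (n < 2) next
    co <- c(1 + 0i)
    for (l in lam) co <- c(co, 0) - c(0, co) * l
    d <- hurwitz_numeric(Re(co))
    oc <- orlando_check(lam)
    expect_equal(oc[["delta_penult"]], d[n - 1], tolerance = 1e-9)
    expect_equal(oc[["delta_last"]], d[n], tolerance = 1e-9)
  }
})

test_that("stability_analysis chains the pipeline with exact substitution", {
  topo <- jm_topology()
  # original parameters: r1 = r2 = r3 = sigma1 = sigma2 = 1 is the unit
  # governor, whose 3-cycle destabilises (rho1 = rho2 = 1 -> stable though)
  res <- stability_analysis(topo, values = list(
    r1 = 1, r2 = 1, r3 = 1, sigma1 = 1, sigma2 = 1, sigma3 = 1))
  expect_equal(res$routh$k, 0)
  res2 <- stability_analysis(topo, values = list(
    r1 = 0.25, r2 = 0.25, r3 = 1, sigma1 = 1, sigma2 = 1, sigma3 = 1))
  expect_equal(res2$routh$k, 2)
})
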