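# Classical network factory, numeric eigenvalue oracle, reproducible random
# instantiation, and a small fixed-step integrator for the level-decomposition
# demonstrations. The six classical fixtures carry the literature's reduced
# expressions verbatim as strings (plus parsed forms) so that any discrepancy
# between a printed expression and the pipeline's own derivation stays
# visible in tests rather than being silently corrected.

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

new_fixture <- function(name, topology, reduced, expected = list(),
                        steady_state = NULL, steady_state_map = NULL,
                        rate_laws = NULL, jac_values = NULL,
                        constants = list(), notes = character(0)) {
  structure(list(name = name, topology = topology, reduced = reduced,
                 expected = expected, steady_state = steady_state,
                 steady_state_map = steady_state_map, rate_laws = rate_laws,
                 jac_values = jac_values, constants = constants,
                 notes = notes),
            class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("<fixture_bundle> ", x$name, "\n", sep = "")
  print(x$topology)
  cat("  reduced dimensionality d = ", x$reduced$d, "\n", sep = "")
  for (nt in x$notes) cat("  note: ", nt, "\n", sep = "")
  invisible(x)
}

#' Classical network fixtures
#'
#' Builds one of six classical oscillator/controller networks as an
#' influence-topology bundle: the symbolic topology, its reduced form (the
#' literature's scaling and temporal-unit choices), the published reduced
#' expressions for the principal minors and Hurwitz determinants, the
#' closed-form steady-state mapping onto the reduced parameters, and the
#' explicit rate laws for numeric cross-checks.
#'
#' Names: `jenkin_maxwell` (governor, 3 species), `van_der_pol` (Lienard
#' form), `lotka_volterra`, `brusselator`, `selkov`, `repressilator`, plus
#' `repressilator_positive` (the activation variant whose 3-cycle is
#' positive).
#'
#' Known transcription caveats are kept, not corrected: the Sel'kov
#' published `b_2` disagrees in the sign of its `sigma2` term with the
#' direct cycle expansion (the bundle flags it `expected_to_differ`), and
#' the published Lotka-Volterra steady-state map (`rho3 = 1/sigma1`) is
#' used verbatim for the steady-state projection.
#'
#' @param name fixture name.
#' @param constants named list overriding the fixture's default rate
#'   constants.
#' @return A `fixture_bundle`.
#' @export
make_classical_network <- function(name, constants = list()) {
  switch(name,
    jenkin_maxwell = fixture_jenkin_maxwell(constants),
    van_der_pol = fixture_van_der_pol(constants),
    lotka_volterra = fixture_lotka_volterra(constants),
    brusselator = fixture_brusselator(constants),
    selkov = fixture_selkov(constants),
    repressilator = fixture_repressilator(constants, positive = FALSE),
    repressilator_positive = fixture_repressilator(constants, positive = TRUE),
    stop("unknown fixture name: ", name)
  )
}

merge_constants <- function(defaults, constants) {
  for (nm in names(constants)) defaults[[nm]] <- constants[[nm]]
  defaults
}

fixture_jenkin_maxwell <- function(constants) {
  cs <- merge_constants(list(k0 = 1, k1 = 1, k2 = 1, k3 = 1,
                             s1 = 1, s2 = 1, s3 = 2), constants)
  if (any(unlist(cs) <= 0)) stop("constants must be positive")
  topo <- build_topology(list(
    v1 = list(inputs = c(x1 = "+r1"), outputs = c(x1 = "-1", x2 = "+sigma1")),
    v2 = list(inputs = c(x3 = "+r2"), outputs = c(x1 = "+sigma2", x3 = "-1")),
    v3 = list(inputs = c(x2 = "+r3"), outputs = c(x3 = "-1")),
    v0 = list(inputs = character(0), outputs = c(x1 = "-1", x3 = "+sigma3"))
  ), species = c("x1", "x2", "x3"))
  reduced <- reduce_topology(topo, unit = "r3")
  new_fixture(
    "jenkin_maxwell", topo, reduced,
    expected = list(
      minors = c(b1 = "-rho1 - rho2", b2 = "rho1*rho2", b3 = "-rho1*rho2"),
      deltas = c(d1 = "rho1 + rho2",
                 d2 = "rho1*rho2*(rho1 + rho2 - 1)",
                 d3 = "rho1^2*rho2^2*(rho1 + rho2 - 1)")
    ),
    steady_state = function(cs) c(
      x1 = 0,
      x2 = cs$k0 * (cs$s3 - 1 / cs$s2) / cs$k3,
      x3 = cs$k0 / (cs$s2 * cs$k2)),
    steady_state_map = function(cs) c(
      rho1 = cs$k1 / (cs$s1 * cs$s2 * cs$k3),
      rho2 = cs$k2 / (cs$s1 * cs$s2 * cs$k3)),
    rate_laws = function(x, cs) c(
      -cs$k0 - cs$k1 * x[1] + cs$s2 * cs$k2 * x[3],
      cs$s1 * cs$k1 * x[1],
      cs$s3 * cs$k0 - cs$k2 * x[3] - cs$k3 * x[2]),
    jac_values = function(cs) c(
      r1 = cs$k1, r2 = cs$k2, r3 = cs$k3,
      sigma1 = cs$s1, sigma2 = cs$s2, sigma3 = cs$s3),
    constants = cs
  )
}

fixture_van_der_pol <- function(constants) {
  cs <- merge_constants(list(k1 = 1, k2 = 1, k3 = 1, s1 = 1), constants)
  if (any(unlist(cs) <= 0)) stop("constants must be positive")
  topo <- build_topology(list(
    v1 = list(inputs = c(x1 = "+r1"), outputs = c(x1 = "+1", x2 = "+sigma1")),
    v2 = list(inputs = c(x1 = "+r2"), outputs = c(x1 = "-1")),
    v3 = list(inputs = c(x2 = "+r3"), outputs = c(x1 = "-1"))
  ), species = c("x1", "x2"))
  reduced <- reduce_topology(topo, unit = "r3")
  new_fixture(
    "van_der_pol", topo, reduced,
    expected = list(
      minors = c(b1 = "rho1 - rho2", b2 = "rho1"),
      deltas = c(d1 = "rho2 - rho1", d2 = "rho1*(rho2 - rho1)")
    ),
    steady_state = function(cs) c(x1 = 0, x2 = 0),
    # the unique steady state projects onto the boundary line rho2 = 0
    steady_state_map = function(cs) c(
      rho1 = cs$k1 / (cs$s1 * cs$k3), rho2 = 0),
    rate_laws = function(x, cs) c(
      cs$k1 * x[1] - cs$k2 * x[1]^3 - cs$k3 * x[2],
      cs$s1 * cs$k1 * x[1]),
    jac_values = function(cs) c(
      r1 = cs$k1, r2 = 3 * cs$k2 * 0^2, r3 = cs$k3, sigma1 = cs$s1),
    constants = cs,
    notes = "steady-state locus is the line rho2 = 0 (r2 vanishes at x1 = 0)"
  )
}

fixture_lotka_volterra <- function(constants) {
  cs <- merge_constants(list(k1 = 1, k2 = 1, k3 = 1, s1 = 1), constants)
  if (any(unlist(cs) <= 0)) stop("constants must be positive")
  topo <- build_topology(list(
    v1 = list(inputs = c(x1 = "+r1"), outputs = c(x1 = "+1")),
    v2 = list(inputs = c(x1 = "+r2", x2 = "+r4"),
              outputs = c(x1 = "-1", x2 = "+sigma1")),
    v3 = list(inputs = c(x2 = "+r3"), outputs = c(x2 = "-1"))
  ), species = c("x1", "x2"))
  reduced <- reduce_topology(topo, unit = "r4")
  new_fixture(
    "lotka_volterra", topo, reduced,
    expected = list(
      minors = c(b1 = "1 + rho1 - rho2 - rho3",
                 b2 = "rho1 + rho2*rho3 - rho1*rho3"),
      deltas = c(d1 = "rho2 + rho3 - rho1 - 1",
                 d2 = "(rho2 + rho3 - rho1 - 1)*(rho1 + rho2*rho3 - rho1*rho3)")
    ),
    steady_state = function(cs) c(
      x1 = cs$k3 / (cs$s1 * cs$k2), x2 = cs$k1 / cs$k2),
    # the published closed-form projection (rho1 = rho2 = k1/(sigma1 k3),
    # rho3 = 1/sigma1); see the bundle notes
    steady_state_map = function(cs) c(
      rho1 = cs$k1 / (cs$s1 * cs$k3),
      rho2 = cs$k1 / (cs$s1 * cs$k3),
      rho3 = 1 / cs$s1),
    rate_laws = function(x, cs) c(
      cs$k1 * x[1] - cs$k2 * x[1] * x[2],
      cs$s1 * cs$k2 * x[1] * x[2] - cs$k3 * x[2]),
    jac_values = function(cs) c(
      r1 = cs$k1, r2 = cs$k1, r4 = cs$k3 / cs$s1, r3 = cs$k3,
      sigma1 = cs$s1),
    constants = cs,
    notes = paste("published steady-state projection (rho3 = 1/sigma1) is kept",
                  "verbatim; direct differentiation of the rate laws gives",
                  "r4 = k3/sigma1, i.e. rho3 = 1, the neutral center")
  )
}

fixture_brusselator <- function(constants) {
  cs <- merge_constants(list(k0 = 1, k1 = 1, k2 = 2, a = 1), constants)
  if (any(unlist(cs) <= 0)) stop("constants must be positive")
  if (cs$k2 <= cs$a) stop("brusselator requires k2 > a")
  topo <- build_topology(list(
    v0 = list(inputs = character(0), outputs = c(x1 = "+1")),
    v1 = list(inputs = c(x1 = "+r0", x2 = "+r1"),
              outputs = c(x1 = "+sigma1", x2 = "-1")),
    v2 = list(inputs = c(x1 = "+r2"), outputs = c(x1 = "-1", x2 = "+sigma2"))
  ), species = c("x1", "x2"))
  reduced <- reduce_topology(topo, choice = c(v1 = "x2", v2 = "x1"),
                             unit = "r0")
  new_fixture(
    "brusselator", topo, reduced,
    expected = list(
      minors = c(b1 = "sigma1 - rho1 - rho2",
                 b2 = "rho1*rho2 - sigma1*sigma2*rho1*rho2"),
      deltas = c(d1 = "rho1 + rho2 - sigma1",
                 d2 = "(rho1 + rho2 - sigma1)*rho1*rho2*(1 - sigma1*sigma2)")
    ),
    steady_state = function(cs) c(
      x1 = cs$k0 / cs$a,
      x2 = cs$a * (cs$k2 - cs$a) / (cs$k1 * cs$k0)),
    steady_state_map = function(cs) c(
      rho1 = cs$k1 * cs$k0^2 / (2 * cs$a^2 * (cs$k2 - cs$a)),
      rho2 = cs$k2 / (2 * (cs$k2 - cs$a)),
      sigma1 = 1,
      sigma2 = (cs$k2 - cs$a) / cs$k2),
    rate_laws = function(x, cs) {
      s2 <- (cs$k2 - cs$a) / cs$k2
      c(cs$k0 + cs$k1 * x[1]^2 * x[2] - cs$k2 * x[1],
        -cs$k1 * x[1]^2 * x[2] + s2 * cs$k2 * x[1])
    },
    jac_values = function(cs) {
      x1s <- cs$k0 / cs$a
      x2s <- cs$a * (cs$k2 - cs$a) / (cs$k1 * cs$k0)
      c(r0 = 2 * cs$k1 * x1s * x2s, r1 = cs$k1 * x1s^2, r2 = cs$k2,
        sigma1 = 1, sigma2 = (cs$k2 - cs$a) / cs$k2)
    },
    constants = cs
  )
}

fixture_selkov <- function(constants) {
  cs <- merge_constants(list(k0 = 1, k1 = 1, k2 = 1, k3 = 1), constants)
  if (any(unlist(cs) <= 0)) stop("constants must be positive")
  topo <- build_topology(list(
    v0 = list(inputs = character(0), outputs = c(x2 = "+1")),
    v1 = list(inputs = c(x1 = "+r0"), outputs = c(x1 = "-1")),
    v2 = list(inputs = c(x1 = "+r1", x2 = "+r2"),
              outputs = c(x1 = "+sigma1", x2 = "-1")),
    v3 = list(inputs = c(x2 = "+r3"), outputs = c(x1 = "+sigma2", x2 = "-1"))
  ), species = c("x1", "x2"))
  reduced <- reduce_topology(topo,
                             choice = c(v1 = "x1", v2 = "x2", v3 = "x2"),
                             unit = "r0")
  new_fixture(
    "selkov", topo, reduced,
    expected = list(
      minors = c(b1 = "-1 + sigma1*rho1 - rho2 - rho3",
                 b2 = "rho2 + rho3 - sigma1*rho1*rho3 - sigma2*rho1*rho3"),
      deltas = c(d1 = "1 + rho2 + rho3 - sigma1*rho1"),
      expected_to_differ = "b2"
    ),
    steady_state = function(cs) {
      x1s <- cs$k0 / cs$k1
      c(x1 = x1s, x2 = cs$k0 / (cs$k2 * x1s^2 + cs$k3))
    },
    steady_state_map = function(cs) c(
      rho1 = 2 / (1 + cs$k1^2 * cs$k3 / (cs$k0^2 * cs$k2)),
      rho2 = cs$k0^2 * cs$k2 / cs$k1^3,
      rho3 = cs$k3 / cs$k1,
      sigma1 = 1, sigma2 = 1),
    rate_laws = function(x, cs) c(
      -cs$k1 * x[1] + cs$k2 * x[1]^2 * x[2] + cs$k3 * x[2],
      cs$k0 - cs$k2 * x[1]^2 * x[2] - cs$k3 * x[2]),
    jac_values = function(cs) {
      x1s <- cs$k0 / cs$k1
      x2s <- cs$k0 / (cs$k2 * x1s^2 + cs$k3)
      c(r0 = cs$k1, r1 = 2 * cs$k2 * x1s * x2s, r2 = cs$k2 * x1s^2,
        r3 = cs$k3, sigma1 = 1, sigma2 = 1)
    },
    constants = cs,
    notes = paste("published b2 has -sigma2*rho1*rho3 where direct cycle",
                  "expansion gives +sigma2*rho1*rho3; the published string is",
                  "stored and flagged expected_to_differ")
  )
}

fixture_repressilator <- function(constants, positive = FALSE) {
  cs <- merge_constants(list(k1 = 1, k2 = 1, k3 = 1, k4 = 1, k5 = 1, k6 = 1,
                             a = 2, b = 2, cc = 2), constants)
  if (any(unlist(cs) <= 0)) stop("constants must be positive")
  jsgn <- if (positive) "+" else "-"
  topo <- build_topology(list(
    v1 = list(inputs = stats::setNames(paste0(jsgn, "r4"), "x1"),
              outputs = c(x2 = "+1")),
    v2 = list(inputs = stats::setNames(paste0(jsgn, "r5"), "x2"),
              outputs = c(x3 = "+1")),
    v3 = list(inputs = stats::setNames(paste0(jsgn, "r6"), "x3"),
              outputs = c(x1 = "+1")),
    v4 = list(inputs = c(x1 = "+r1"), outputs = c(x1 = "-1")),
    v5 = list(inputs = c(x2 = "+r2"), outputs = c(x2 = "-1")),
    v6 = list(inputs = c(x3 = "+r3"), outputs = c(x3 = "-1"))
  ), species = c("x1", "x2", "x3"))
  reduced <- reduce_topology(topo, unit = "r4")
  expected <- if (!positive) list(
    minors = c(b1 = "-rho1 - rho2 - rho3",
               b2 = "rho1*rho2 + rho1*rho3 + rho2*rho3",
               b3 = "-rho1*rho2*rho3 - 1"),
    deltas = c(
      d1 = "rho1 + rho2 + rho3",
      d2 = "(rho1 + rho2 + rho3)*(rho1*rho2 + rho1*rho3 + rho2*rho3) - rho1*rho2*rho3 - 1",
      d3 = "(rho1*rho2*rho3 + 1)*((rho1 + rho2 + rho3)*(rho1*rho2 + rho1*rho3 + rho2*rho3) - rho1*rho2*rho3 - 1)")
  ) else list(
    minors = c(b1 = "-rho1 - rho2 - rho3",
               b2 = "rho1*rho2 + rho1*rho3 + rho2*rho3",
               b3 = "-rho1*rho2*rho3 + 1"),
    deltas = c(
      d1 = "rho1 + rho2 + rho3",
      d2 = "(rho1 + rho2 + rho3)*(rho1*rho2 + rho1*rho3 + rho2*rho3) - rho1*rho2*rho3 + 1",
      d3 = "(rho1*rho2*rho3 - 1)*((rho1 + rho2 + rho3)*(rho1*rho2 + rho1*rho3 + rho2*rho3) - rho1*rho2*rho3 + 1)")
  )
  hill <- function(x, n) 1 / (1 + x^n)
  new_fixture(
    if (positive) "repressilator_positive" else "repressilator",
    topo, reduced, expected = expected,
    rate_laws = if (!positive) function(x, cs) c(
      cs$k3 * hill(x[3], cs$cc) - cs$k4 * x[1],
      cs$k1 * hill(x[1], cs$a) - cs$k5 * x[2],
      cs$k2 * hill(x[2], cs$b) - cs$k6 * x[3]) else NULL,
    jac_values = NULL,   # no closed-form steady state (Hill-coefficient dependent)
    constants = cs
  )
}

#' Single n-cycle fixtures
#'
#' The network consisting of one bipartite cycle through `n` species and
#' `n` reactions. After compaction and temporal scaling the whole cycle is
#' the single number `c_n = +/-1`. For even `n` every Hurwitz determinant
#' vanishes (no first-order information); for odd `n` only the last two are
#' nonzero, `Delta_{n-1} = (-1)^((n+1)/2) c_n^((n-1)/2)` and
#' `Delta_n = -(-1)^((n+1)/2) c_n^((n+1)/2)`, giving
#' `k = (n + (-1)^((n-1)/2) c_n) / 2` unstable roots.
#'
#' @param n cycle length (>= 1).
#' @param cycle_sign overall cycle sign, +1 or -1.
#' @return A `fixture_bundle` with `expected$deltas_num` and `expected$k`.
#' @export
make_ncycle <- function(n, cycle_sign = 1) {
  stopifnot(n >= 1, cycle_sign %in% c(1, -1))
  ids <- sprintf("x%02d", 1:n)
  rids <- sprintf("v%02d", 1:n)
  rx <- list()
  for (i in 1:n) {
    nxt <- if (i == n) 1 else i + 1
    out_sign <- if (i == n && cycle_sign < 0) "-1" else "+1"
    rx[[rids[i]]] <- list(
      inputs = stats::setNames(paste0("+c", sprintf("%02d", i)), ids[i]),
      outputs = stats::setNames(out_sign, ids[nxt]))
  }
  topo <- build_topology(rx, species = ids)
  reduced <- reduce_topology(topo)
  expected <- if (n %% 2 == 0) {
    list(deltas_num = rep(0, n), k = NA_integer_, indeterminate = TRUE)
  } else if (n == 1) {
    list(deltas_num = -cycle_sign, k = if (cycle_sign > 0) 1L else 0L,
         indeterminate = FALSE)
  } else {
    # Delta_{n-1} = (-1)^floor(n/4) c^((n-1)/2); Delta_n = -c Delta_{n-1}.
    # (The often-quoted closed form with sign (-1)^((n+1)/2) holds for
    # n = 3, 5 but flips for n = 7, 9, ...: the sign has period 4 in n, as
    # both the determinant expansion and Orlando's product confirm. The
    # unstable-root count below is unaffected.)
    sgn <- (-1)^floor(n / 4)
    dpen <- sgn * cycle_sign^((n - 1) / 2)
    list(deltas_num = c(rep(0, n - 2), dpen, -cycle_sign * dpen),
         k = as.integer((n + (-1)^((n - 1) / 2) * cycle_sign) / 2),
         indeterminate = FALSE)
  }
  new_fixture(paste0("ncycle_", n, if (cycle_sign < 0) "_neg" else "_pos"),
              topo, reduced, expected = expected,
              constants = list(n = n, cycle_sign = cycle_sign))
}

#' Numeric eigenvalue oracle
#'
#' Full spectrum of a numeric transition matrix, the count of eigenvalues
#' with positive real part, and the stability margin (smallest |Re lambda|)
#' so callers can exclude boundary cases.
#'
#' @param H numeric square matrix.
#' @return An `oracle_result`: `eigenvalues`, `unstable_count`, `margin`.
#' @export
eigen_oracle <- function(H) {
  if (!all(is.finite(H))) stop("non-finite entries in transition matrix")
  ev <- eigen(H, only.values = TRUE)$values
  structure(list(eigenvalues = ev,
                 unstable_count = sum(Re(ev) > 0),
                 margin = min(abs(Re(ev)))),
            class = "oracle_result")
}

#' @export
print.oracle_result <- function(x, ...) {
  cat("<oracle_result> ", x$unstable_count, " unstable eigenvalue(s), margin ",
      format(x$margin, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Reproducible random edge weights
#'
#' Draws a positive magnitude for every symbolic edge weight of a topology,
#' log-uniformly on `[0.1, 10]`; the same seed gives the same assignment and
#' the global RNG state is left untouched.
#'
#' @param topo an `influence_topology`.
#' @param seed integer seed.
#' @return Named numeric vector (symbol name to magnitude).
#' @export
random_instantiation <- function(topo, seed) {
  syms <- sort(unique(stats::na.omit(c(topo$jac$w_sym, topo$stoich$w_sym))))
  with_seed_local(seed, {
    stats::setNames(10^stats::runif(length(syms), -1, 1), syms)
  })
}

#' Random fixed-sign topologies for property checks
#'
#' Seed-controlled generator of small connected-ish reaction networks with
#' random signs and random small-rational edge weights (so downstream cycle
#' algebra stays exact).
#'
#' @param n number of species.
#' @param m number of reactions.
#' @param seed integer seed.
#' @return An `influence_topology`.
#' @export
random_topology <- function(n, m, seed) {
  with_seed_local(seed, {
    sp <- sprintf("x%02d", 1:n)
    rx <- list()
    for (k in 1:m) {
      n_in <- sample(1:min(2, n), 1)
      n_out <- sample(1:min(2, n), 1)
      ins <- sample(sp, n_in)
      outs <- sample(sp, n_out)
      wstr <- function() {
        s <- sample(c("+", "-"), 1)
        paste0(s, sample(1:9, 1), "/", sample(1:4, 1))
      }
      rx[[sprintf("v%02d", k)]] <- list(
        inputs = stats::setNames(vapply(ins, function(i) wstr(), ""), ins),
        outputs = stats::setNames(vapply(outs, function(i) wstr(), ""), outs))
    }
    build_topology(rx, species = sp)
  })
}

#' Fixed-step trajectory integration
#'
#' Classical fourth-order Runge-Kutta at a fixed step (via deSolve), with a
#' divergence flag once any species magnitude exceeds `1e9`. Intended for
#' qualitative demonstrations of level-decomposition dynamics, not for
#' quantitative integration.
#'
#' @param rate_laws function `(x) -> dx/dt` (or `(x, constants)`, see
#'   `constants`).
#' @param initial named numeric initial state.
#' @param horizon end time.
#' @param step fixed step size.
#' @param constants optional second argument passed to `rate_laws`.
#' @return A tibble (`time` plus one column per species) with attribute
#'   `diverged`.
#' @export
simulate_trajectories <- function(rate_laws, initial, horizon, step = 1e-3,
                                  constants = NULL) {
  stopifnot(step > 0, all(is.finite(initial)))
  f <- function(t, y, p) {
    dy <- if (is.null(constants)) rate_laws(y) else rate_laws(y, constants)
    list(dy)
  }
  times <- seq(0, horizon, by = step)
  out <- deSolve::ode(y = initial, times = times, func = f, parms = NULL,
                      method = "rk4")
  out <- as.data.frame(out)
  vals <- as.matrix(out[, -1, drop = FALSE])
  bad <- !is.finite(vals) | abs(vals) > 1e9
  diverged <- any(bad)
  if (diverged) {
    first_bad <- min(which(apply(bad, 1, any)))
    out <- out[seq_len(max(1, first_bad - 1)), , drop = FALSE]
  }
  res <- tibble::as_tibble(out)
  names(res)[1] <- "time"
  attr(res, "diverged") <- diverged
  res
}
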