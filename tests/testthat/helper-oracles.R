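# Independent oracles used across the suite.

p_det_ <- function(M) cyclostab:::p_det(M)
p_eq_ <- function(a, b) cyclostab:::p_equal(a, b)
p_num_ <- function(p) cyclostab:::p_to_num(p)
p_const_ <- function(p) cyclostab:::p_is_const(p)

# brute-force principal minors: sums of q x q principal subdeterminants of
# the (exact) transition matrix, by cofactor expansion -- the Leibniz route,
# independent of the cycle machinery
minors_brute <- function(topo, values = NULL) {
  H <- cyclostab:::transition_matrix_poly(topo, values)
  n <- nrow(H)
  out <- vector("list", n + 1)
  out[[1]] <- poly_const(1)
  for (q in 1:n) {
    acc <- poly_const(0)
    for (sub in utils::combn(n, q, simplify = FALSE)) {
      acc <- acc + p_det_(H[sub, sub, drop = FALSE])
    }
    out[[q + 1]] <- acc
  }
  out
}

# numeric principal minors of a plain matrix
minors_numeric <- function(M) {
  n <- nrow(M)
  b <- c(1, vapply(1:n, function(q) {
    sum(vapply(utils::combn(n, q, simplify = FALSE), function(sub)
      det(M[sub, sub, drop = FALSE]), numeric(1)))
  }, numeric(1)))
  b
}

# numeric Hurwitz determinants from charpoly coefficients a_0..a_n
hurwitz_numeric <- function(a) {
  n <- length(a) - 1
  vapply(1:n, function(q) {
    M <- matrix(0, q, q)
    for (i in 1:q) for (j in 1:q) {
      idx <- 2 * i - j
      if (idx >= 0 && idx <= n) M[i, j] <- a[idx + 1]
    }
    det(M)
  }, numeric(1))
}

# central finite-difference transition matrix H[i, j] = d f_j / d x_i
fd_transition <- function(f, x, h = 1e-6) {
  n <- length(x)
  H <- matrix(0, n, n)
  for (i in 1:n) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    H[i, ] <- (f(xp) - f(xm)) / (2 * h)
  }
  H
}

jm_topology <- function() {
  make_classical_network("jenkin_maxwell")$topology
}

fixture_names <- c("jenkin_maxwell", "van_der_pol", "lotka_volterra",
                   "brusselator", "selkov", "repressilator")

# a reduced topology usable where a scan needs >= 1 axis but trivial
# stability: two independent decay 1-cycles
double_decay_topology <- function() {
  build_topology(list(
    v1 = list(inputs = c(x1 = "+r1"), outputs = c(x1 = "-1")),
    v2 = list(inputs = c(x2 = "+r2"), outputs = c(x2 = "-1"))
  ), species = c("x1", "x2"))
}
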