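# Characteristic-polynomial coefficients, Hurwitz determinants and the
# Routh unstable-root count, including the degenerate cases where strings of
# Hurwitz determinants vanish exactly.

#' Characteristic polynomial coefficients from principal minors
#'
#' `a_q = (-1)^q b_q`, with `a_0 = b_0 = 1` for the monic characteristic
#' polynomial of the transition matrix.
#'
#' @param minors a `minor_set` (or a plain list of `cpoly` `b_0..b_n`).
#' @return List of `cpoly` coefficients `a` with `a[[q+1]] = a_q`.
#' @export
charpoly_coefficients <- function(minors) {
  b <- if (inherits(minors, "minor_set")) minors$b else minors
  if (!p_equal(as_cpoly(b[[1]]), p_one()))
    stop("b_0 must equal 1")
  lapply(seq_along(b), function(i) p_scale(as_cpoly(b[[i]]), (-1)^(i - 1)))
}

hurwitz_matrix <- function(a, q) {
  # entry (i, j) is a_{2i - j}; indices outside 0..n are zero
  n <- length(a) - 1
  M <- matrix(rep(list(p_zero()), q * q), nrow = q, ncol = q)
  for (i in seq_len(q)) for (j in seq_len(q)) {
    idx <- 2 * i - j
    if (idx >= 0 && idx <= n) M[[i, j]] <- a[[idx + 1]]
  }
  M
}

new_hurwitz_result <- function(deltas) {
  structure(list(
    deltas = deltas,
    negative_terms = lapply(deltas, p_negative_terms)
  ), class = "hurwitz_result")
}

#' Hurwitz determinants
#'
#' `Delta_q` is the determinant of the `q x q` matrix with entries
#' `a_{2i-j}` (zero outside `0..n`), computed exactly by cofactor expansion
#' over the rational polynomial ring. All `Delta_q > 0` is necessary and
#' sufficient for local asymptotic stability. Monomials with negative
#' coefficients (parameters being positive symbols) are the candidate
#' destabilising "multiplicative topologies" and are reported per
#' determinant.
#'
#' @param coeffs list of `cpoly` coefficients from
#'   [charpoly_coefficients()], or a `minor_set` (converted on the fly).
#' @return A `hurwitz_result`: `deltas` (list of `cpoly`,
#'   `deltas[[q]] = Delta_q`) and `negative_terms` (per-determinant tibbles
#'   of negative monomials).
#' @export
hurwitz_determinants <- function(coeffs) {
  if (inherits(coeffs, "minor_set")) coeffs <- charpoly_coefficients(coeffs)
  a <- lapply(coeffs, as_cpoly)
  n <- length(a) - 1
  deltas <- lapply(seq_len(n), function(q) p_det(hurwitz_matrix(a, q)))
  new_hurwitz_result(deltas)
}

#' Hurwitz determinants directly from principal minors
#'
#' Uses the explicit low-order templates
#' `Delta_1 = -b_1`, `Delta_2 = -b_1 b_2 + b_0 b_3`,
#' `Delta_3 = b_1 b_2 b_3 - b_0 b_3^2 + b_0 b_1 b_5 - b_1^2 b_4` and the
#' order-4 analogue, which make the cycle-product structure of each
#' determinant visible; beyond `n = 4` the determinant route is used. Values
#' agree exactly with [hurwitz_determinants()].
#'
#' @param minors a `minor_set`.
#' @return A `hurwitz_result`.
#' @export
hurwitz_from_cycles <- function(minors) {
  stopifnot(inherits(minors, "minor_set"))
  n <- minors$n
  if (n > 4) return(hurwitz_determinants(minors))
  bq <- function(q) if (q <= n) as_cpoly(minors$b[[q + 1]]) else p_zero()
  b0 <- bq(0); b1 <- bq(1); b2 <- bq(2); b3 <- bq(3); b4 <- bq(4)
  b5 <- p_zero(); b6 <- p_zero(); b7 <- p_zero()
  deltas <- list()
  if (n >= 1) deltas[[1]] <- p_neg(b1)
  if (n >= 2) deltas[[2]] <- p_add(p_neg(p_mul(b1, b2)), p_mul(b0, b3))
  if (n >= 3) deltas[[3]] <- p_sum(list(
    p_prod(list(b1, b2, b3)),
    p_neg(p_prod(list(b0, b3, b3))),
    p_prod(list(b0, b1, b5)),
    p_neg(p_prod(list(b1, b1, b4)))
  ))
  if (n >= 4) deltas[[4]] <- p_sum(list(
    p_prod(list(b1, b2, b3, b4)),
    p_neg(p_prod(list(b0, b3, b3, b4))),
    p_neg(p_prod(list(b1, b1, b4, b4))),
    p_neg(p_prod(list(b1, b2, b2, b5))),
    p_prod(list(b0, b2, b3, b5)),
    p_scale(p_prod(list(b0, b1, b4, b5)), 2),
    p_neg(p_prod(list(b0, b0, b5, b5))),
    p_prod(list(b1, b1, b2, b6)),
    p_neg(p_prod(list(b0, b1, b3, b6))),
    p_neg(p_prod(list(b0, b1, b2, b7))),
    p_prod(list(b0, b0, b3, b7))
  ))
  new_hurwitz_result(deltas)
}

#' @export
print.hurwitz_result <- function(x, ...) {
  cat("<hurwitz_result> n =", length(x$deltas), "\n")
  for (q in seq_along(x$deltas)) {
    cat("  Delta_", q, " = ", format(x$deltas[[q]]), "\n", sep = "")
    nt <- x$negative_terms[[q]]
    if (nrow(nt) > 0)
      cat("    negative terms: ",
          paste0(fmt_coef(nt$coef_num, nt$coef_den), "*", nt$term,
                 collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a Hurwitz result
#' @param x a `hurwitz_result`.
#' @param ... unused.
#' @return Tibble with `q`, `expression` and the negative monomials
#'   (destabilising multiplicative topologies) per determinant.
#' @method tidy hurwitz_result
#' @export
tidy.hurwitz_result <- function(x, ...) {
  tibble::tibble(
    q = seq_along(x$deltas),
    expression = vapply(x$deltas, format, character(1)),
    negative_terms = vapply(x$negative_terms, function(nt)
      if (nrow(nt) == 0) "" else
        paste0(fmt_coef(nt$coef_num, nt$coef_den), "*", nt$term,
               collapse = "; "), character(1))
  )
}

# exact signs (-1, 0, +1) from a hurwitz_result / cpoly / rational inputs,
# tolerance-based from doubles
delta_signs <- function(deltas, tol = NULL) {
  if (inherits(deltas, "hurwitz_result")) deltas <- deltas$deltas
  if (is.numeric(deltas)) {
    if (any(!is.finite(deltas))) stop("non-finite Hurwitz determinant")
    tol <- tol %||% (1e-9 * (1 + cummax(abs(deltas))))
    return(as.integer(sign(deltas)) * as.integer(abs(deltas) > tol))
  }
  vapply(deltas, function(d) {
    d <- as_cpoly(d)
    if (!p_is_const(d))
      stop("symbolic Hurwitz determinant: substitute numeric values first")
    p_sign(d)
  }, integer(1))
}

#' Count unstable roots from the Hurwitz determinants
#'
#' The number of eigenvalues with positive real part equals the number of
#' sign changes in the Routh first column `(a_0, Delta_1, Delta_2/Delta_1,
#' ..., Delta_n/Delta_{n-1})`. Exact zeros are handled: a string of zeros
#' terminating at `Delta_n` truncates the array; an interior or leading
#' string of `p` zeros (p odd) contributes `(p+1)/2` changes plus a parity
#' correction from the signs flanking the string. If every determinant is
#' zero the first-order analysis carries no information and the count is
#' reported as indeterminate.
#'
#' @param deltas `hurwitz_result`, list of constant `cpoly` (exact), or
#'   numeric vector (tolerance `|Delta| <= 1e-9 * (1 + running magnitude)`
#'   treats a value as zero).
#' @param a0 sign of the leading coefficient (+1 for the monic convention).
#' @param tol optional numeric zero tolerance override.
#' @return A `routh_count`: `k` (integer, `NA` when indeterminate),
#'   `indeterminate`, `zero_strings` tibble (`start`, `length`),
#'   `truncated`.
#' @export
count_unstable_roots <- function(deltas, a0 = 1L, tol = NULL) {
  s <- delta_signs(deltas, tol = tol)
  a0s <- as.integer(sign(a0))
  if (a0s == 0) stop("a0 must be nonzero")
  n <- length(s)
  zero_strings <- tibble::tibble(start = integer(), length = integer())
  rl <- rle(s == 0)
  pos <- cumsum(c(1, rl$lengths))
  for (i in seq_along(rl$values)) if (rl$values[i]) {
    zero_strings <- dplyr::bind_rows(zero_strings, tibble::tibble(
      start = as.integer(pos[i]), length = as.integer(rl$lengths[i])))
  }

  if (all(s == 0)) {
    return(structure(list(k = NA_integer_, indeterminate = TRUE,
                          zero_strings = zero_strings, truncated = FALSE,
                          n = n), class = "routh_count"))
  }
  truncated <- FALSE
  while (length(s) > 0 && s[length(s)] == 0) {
    truncated <- TRUE
    s <- s[-length(s)]
  }

  # entry_sign(i): sign of the i-th Routh first-column entry over signs s
  entry <- function(i) {
    if (i == 0) return(a0s)
    if (i == 1) return(s[1])
    s[i] * s[i - 1]
  }
  count_changes <- function(entries) {
    entries <- entries[entries != 0]
    if (length(entries) < 2) return(0L)
    sum(diff(entries) != 0)
  }

  count_from <- function(start) {
    # counts sign changes among entries start..length(s), handling zero runs
    m <- length(s)
    zpos <- which(s == 0 & seq_along(s) >= start)
    if (length(zpos) == 0) {
      ent <- vapply(start:m, entry, numeric(1))
      if (start == 1) ent <- c(a0s, ent)
      return(count_changes(ent))
    }
    z <- zpos[1]
    sidx <- z - 1                       # last nonzero index before the run
    p <- 0
    while (z + p <= m && s[z + p] == 0) p <- p + 1
    if (p %% 2 == 0)
      stop("even-length interior zero string: Routh count undefined")
    after <- sidx + p + 1               # first nonzero after the run
    if (after + 1 > m)
      stop("zero string too close to Delta_n for the Routh correction")
    head_entries <- if (sidx >= start) vapply(start:sidx, entry, numeric(1))
                    else numeric(0)
    if (start == 1) head_entries <- c(a0s, head_entries)
    head_v <- count_changes(head_entries)
    e_s <- entry(sidx)                  # entry(0) = a0 when the run leads
    e_after2 <- s[after + 1] * s[after]
    sgn_term <- sign(e_s * e_after2)
    corr <- (p + 1) / 2 +
      (1 - (-1)^((p + 1) / 2) * sgn_term) / 2
    head_v + corr + count_from(after + 1)
  }

  k <- as.integer(count_from(1))
  structure(list(k = k, indeterminate = FALSE, zero_strings = zero_strings,
                 truncated = truncated, n = n), class = "routh_count")
}

#' @export
print.routh_count <- function(x, ...) {
  if (x$indeterminate) {
    cat("<routh_count> indeterminate at first order (all Hurwitz determinants zero)\n")
  } else {
    cat("<routh_count> k =", x$k, "unstable root(s)\n")
  }
  if (nrow(x$zero_strings) > 0)
    cat("  zero strings at Delta_",
        paste0(x$zero_strings$start, " (length ", x$zero_strings$length, ")",
               collapse = ", Delta_"), "\n", sep = "")
  if (x$truncated) cat("  trailing zero string truncated\n")
  invisible(x)
}

#' One-row Routh summary
#' @param x a `routh_count`.
#' @param ... unused.
#' @method glance routh_count
#' @export
glance.routh_count <- function(x, ...) {
  tibble::tibble(k = x$k, indeterminate = x$indeterminate,
                 n = x$n, truncated = x$truncated,
                 n_zero_strings = nrow(x$zero_strings))
}

#' Orlando cross-check of the last two Hurwitz determinants
#'
#' From a spectrum `lambda_1..lambda_n`:
#' `Delta_{n-1} = (-1)^(n(n-1)/2) a_0^(n-1) prod_{i<k} (lambda_i + lambda_k)`
#' and `Delta_n = a_n Delta_{n-1}` with `a_n = prod(-lambda_i)`. Both vanish
#' together exactly when a purely imaginary pair is present (the Hopf
#' necessity). Note the product form for `Delta_n` as printed in some
#' references disagrees in sign with `a_n Delta_{n-1}` for odd `n`; the
#' recurrence form is used here since the determinant definition satisfies
#' it identically.
#'
#' @param eigenvalues complex (or numeric) vector of length `n >= 1`.
#' @param a0 leading coefficient (1 for monic).
#' @return Named numeric vector `c(delta_penult, delta_last)` (real parts;
#'   imaginary residue beyond 1e-8 relative is an error).
#' @export
orlando_check <- function(eigenvalues, a0 = 1) {
  lam <- as.complex(eigenvalues)
  n <- length(lam)
  if (n < 1) stop("need at least one eigenvalue")
  if (n == 1) {
    d1 <- Re(-lam[1]) * a0
    return(c(delta_penult = a0, delta_last = d1))
  }
  pr <- 1 + 0i
  for (i in 1:(n - 1)) for (k in (i + 1):n) pr <- pr * (lam[i] + lam[k])
  dpen <- (-1)^(n * (n - 1) / 2) * a0^(n - 1) * pr
  an <- a0 * prod(-lam)
  dlast <- an * dpen
  res <- c(dpen, dlast)
  scale <- pmax(abs(res), 1)
  if (any(abs(Im(res)) > 1e-8 * scale))
    stop("non-real Orlando product: spectrum is not closed under conjugation")
  c(delta_penult = Re(dpen), delta_last = Re(dlast))
}

#' Stability report for a topology at numeric parameter values
#'
#' Convenience wrapper: minors, characteristic coefficients, Hurwitz
#' determinants and the Routh count, all exact when the substituted values
#' are rationals.
#'
#' @param topo fixed-sign `influence_topology`.
#' @param values named list/vector: symbol name to value (numeric, or
#'   `c(num, den)` handled via rationalization); `NULL` if all edge weights
#'   are numeric.
#' @return List with `minors`, `coeffs`, `hurwitz`, `routh`.
#' @export
stability_analysis <- function(topo, values = NULL) {
  minors <- principal_minors(topo)
  if (!is.null(values)) {
    subs <- lapply(values, as_cpoly)
    minors$b <- lapply(minors$b, p_subst, subs = subs)
  }
  coeffs <- charpoly_coefficients(minors$b)
  hw <- hurwitz_determinants(coeffs)
  rc <- if (all(vapply(hw$deltas, p_is_const, logical(1))))
    count_unstable_roots(hw) else NULL
  list(minors = minors, coeffs = coeffs, hurwitz = hw, routh = rc)
}
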