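# Exact multivariate polynomials over the rationals.
#
# The whole topological stability calculus (principal minors as cycle sums,
# Hurwitz determinants, Routh zero-string logic) branches on *exact* zeros,
# so every symbolic quantity in the package is a `cpoly`: a normalised sum of
# monomials in named parameters with rational coefficients. Integers are kept
# in doubles, which are exact below 2^53; all core operations stop with an
# error if that range is exceeded (grid evaluation uses a guarded variant
# that signals overflow instead, see `poly_eval_rq()`).

MAXINT <- 2^53

rq_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

# normalise a rational pair c(num, den)
rq <- function(n, d = 1) {
  if (d == 0) stop("zero denominator")
  if (d < 0) { n <- -n; d <- -d }
  if (n == 0) return(c(0, 1))
  g <- rq_gcd(n, d)
  c(n / g, d / g)
}

rq_chk <- function(x) {
  if (abs(x[1]) > MAXINT || x[2] > MAXINT)
    stop("exact rational arithmetic overflow", call. = FALSE)
  x
}

rq_add <- function(a, b) rq_chk(rq(a[1] * b[2] + b[1] * a[2], a[2] * b[2]))
rq_mul <- function(a, b) rq_chk(rq(a[1] * b[1], a[2] * b[2]))

# rationalize a double: exact integers pass through, otherwise nearest
# rational by continued fractions with denominator <= max_den
rationalize <- function(x, max_den = 1e6) {
  if (!is.finite(x)) stop("non-finite value cannot be rationalized")
  if (x == round(x)) return(c(x, 1))
  sign <- if (x < 0) -1 else 1
  x <- abs(x)
  h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1; b <- x
  repeat {
    a <- floor(b)
    h2 <- a * h1 + h0; k2 <- a * k1 + k0
    if (k2 > max_den) break
    h0 <- h1; h1 <- h2; k0 <- k1; k1 <- k2
    frac <- b - a
    if (frac < 1e-14) break
    b <- 1 / frac
  }
  rq(sign * h1, k1)
}

mono_key <- function(pow) {
  if (length(pow) == 0) return("")
  paste(names(pow), pow, sep = "^", collapse = "*")
}

new_cpoly <- function(coefn, coefd, pows) {
  keys <- vapply(pows, mono_key, character(1))
  if (anyDuplicated(keys)) {
    idx <- split(seq_along(keys), keys)
    coefn2 <- numeric(length(idx)); coefd2 <- numeric(length(idx))
    pows2 <- vector("list", length(idx))
    for (i in seq_along(idx)) {
      acc <- c(0, 1)
      for (j in idx[[i]]) acc <- rq_add(acc, c(coefn[j], coefd[j]))
      coefn2[i] <- acc[1]; coefd2[i] <- acc[2]
      pows2[[i]] <- pows[[idx[[i]][1]]]
    }
    coefn <- coefn2; coefd <- coefd2; pows <- pows2
    keys <- names(idx)
  }
  keep <- coefn != 0
  coefn <- coefn[keep]; coefd <- coefd[keep]
  pows <- pows[keep]; keys <- keys[keep]
  o <- order(keys)
  structure(list(coefn = coefn[o], coefd = coefd[o],
                 pows = pows[o], keys = keys[o]),
            class = "cpoly")
}

#' Polynomial constant
#'
#' Exact rational constant `n/d` as a polynomial with no variables.
#' @param n,d integer-valued numerator and denominator.
#' @return A `cpoly` object.
#' @export
poly_const <- function(n, d = 1) {
  r <- rq(n, d)
  new_cpoly(r[1], r[2], list(numeric(0)))
}

#' Polynomial symbol
#'
#' A single named parameter, treated as a strictly positive real in all
#' sign reasoning downstream.
#' @param name variable name.
#' @return A `cpoly` object.
#' @export
poly_sym <- function(name) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  pow <- stats::setNames(1, name)
  new_cpoly(1, 1, list(pow))
}

p_zero <- function() new_cpoly(numeric(0), numeric(0), list())
p_one <- function() poly_const(1)

is_cpoly <- function(x) inherits(x, "cpoly")

as_cpoly <- function(x) {
  if (is_cpoly(x)) return(x)
  if (is.numeric(x) && length(x) == 1) {
    r <- rationalize(x)
    return(poly_const(r[1], r[2]))
  }
  stop("cannot coerce to cpoly")
}

p_add <- function(a, b) {
  new_cpoly(c(a$coefn, b$coefn), c(a$coefd, b$coefd), c(a$pows, b$pows))
}

p_neg <- function(a) {
  a$coefn <- -a$coefn
  a
}

p_sub <- function(a, b) p_add(a, p_neg(b))

pow_mul <- function(p1, p2) {
  if (length(p1) == 0) return(p2)
  if (length(p2) == 0) return(p1)
  vars <- union(names(p1), names(p2))
  out <- stats::setNames(numeric(length(vars)), vars)
  out[names(p1)] <- p1
  out[names(p2)] <- out[names(p2)] + p2
  out <- out[out != 0]
  out[order(names(out))]
}

p_mul <- function(a, b) {
  na <- length(a$coefn); nb <- length(b$coefn)
  if (na == 0 || nb == 0) return(p_zero())
  coefn <- numeric(na * nb); coefd <- numeric(na * nb)
  pows <- vector("list", na * nb)
  k <- 0
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    k <- k + 1
    r <- rq_mul(c(a$coefn[i], a$coefd[i]), c(b$coefn[j], b$coefd[j]))
    coefn[k] <- r[1]; coefd[k] <- r[2]
    pows[[k]] <- pow_mul(a$pows[[i]], b$pows[[j]])
  }
  new_cpoly(coefn, coefd, pows)
}

p_pow <- function(a, n) {
  stopifnot(n >= 0, n == round(n))
  out <- p_one()
  while (n > 0) { out <- p_mul(out, a); n <- n - 1 }
  out
}

p_scale <- function(a, n, d = 1) p_mul(a, poly_const(n, d))

p_sum <- function(xs) Reduce(p_add, xs, p_zero())
p_prod <- function(xs) Reduce(p_mul, xs, p_one())

#' @export
Ops.cpoly <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-") return(p_neg(e1))
    if (.Generic == "+") return(e1)
    stop("unsupported unary operator for cpoly: ", .Generic)
  }
  if (.Generic == "^") return(p_pow(as_cpoly(e1), e2))
  if (.Generic == "==") return(p_equal(as_cpoly(e1), as_cpoly(e2)))
  if (.Generic == "!=") return(!p_equal(as_cpoly(e1), as_cpoly(e2)))
  if (.Generic == "/") {
    e2 <- as_cpoly(e2)
    if (!p_is_const(e2) || p_is_zero(e2))
      stop("cpoly division only by nonzero constants")
    return(p_scale(as_cpoly(e1), e2$coefd[1], e2$coefn[1]))
  }
  a <- as_cpoly(e1); b <- as_cpoly(e2)
  switch(.Generic,
         "+" = p_add(a, b),
         "-" = p_sub(a, b),
         "*" = p_mul(a, b),
         stop("unsupported operator for cpoly: ", .Generic))
}

#' Variables of a polynomial
#' @param p a `cpoly`.
#' @return Character vector of variable names.
#' @export
poly_vars <- function(p) {
  sort(unique(unlist(lapply(p$pows, names))))
}

p_is_zero <- function(p) length(p$coefn) == 0

#' Test a polynomial for exact zero
#' @param p a `cpoly`.
#' @export
poly_is_zero <- function(p) p_is_zero(p)

p_is_const <- function(p) {
  length(p$coefn) == 0 || (length(p$coefn) == 1 && length(p$pows[[1]]) == 0)
}

# exact sign of a constant polynomial
p_sign <- function(p) {
  if (p_is_zero(p)) return(0L)
  if (!p_is_const(p)) stop("sign of a non-constant polynomial")
  as.integer(sign(p$coefn[1]))
}

p_to_num <- function(p) {
  if (p_is_zero(p)) return(0)
  if (!p_is_const(p)) stop("not a constant polynomial")
  p$coefn[1] / p$coefd[1]
}

p_equal <- function(a, b) p_is_zero(p_sub(a, b))

#' Exact equality of two polynomials
#' @param a,b `cpoly` objects.
#' @export
poly_equal <- function(a, b) p_equal(as_cpoly(a), as_cpoly(b))

p_subst <- function(p, subs) {
  out <- p_zero()
  for (i in seq_along(p$coefn)) {
    term <- poly_const(p$coefn[i], p$coefd[i])
    pw <- p$pows[[i]]
    for (v in names(pw)) {
      base <- if (v %in% names(subs)) as_cpoly(subs[[v]]) else poly_sym(v)
      term <- p_mul(term, p_pow(base, pw[[v]]))
    }
    out <- p_add(out, term)
  }
  out
}

#' Substitute into a polynomial
#'
#' @param p a `cpoly`.
#' @param subs named list: variable name to `cpoly` or numeric replacement.
#'   Variables absent from `subs` are left symbolic.
#' @return A `cpoly`.
#' @export
poly_subst <- function(p, subs) p_subst(p, subs)

# numeric (double) evaluation; vals is a named numeric vector
p_eval_num <- function(p, vals) {
  if (p_is_zero(p)) return(0)
  tot <- 0
  for (i in seq_along(p$coefn)) {
    term <- p$coefn[i] / p$coefd[i]
    pw <- p$pows[[i]]
    for (v in names(pw)) {
      if (is.na(vals[v])) stop("missing value for variable: ", v)
      term <- term * unname(vals[v])^pw[[v]]
    }
    tot <- tot + term
  }
  tot
}

# exact rational evaluation, vals = named list of c(num, den) pairs.
# Returns c(num, den) or NULL if the exact route would overflow 2^53.
p_eval_rq <- function(p, vals) {
  acc <- c(0, 1)
  for (i in seq_along(p$coefn)) {
    term <- c(p$coefn[i], p$coefd[i])
    pw <- p$pows[[i]]
    for (v in names(pw)) {
      val <- vals[[v]]
      if (is.null(val)) stop("missing value for variable: ", v)
      for (e in seq_len(pw[[v]])) {
        term <- tryCatch(rq_mul(term, val), error = function(e) NULL)
        if (is.null(term)) return(NULL)
      }
    }
    acc <- tryCatch(rq_add(acc, term), error = function(e) NULL)
    if (is.null(acc)) return(NULL)
  }
  acc
}

#' Evaluate a polynomial numerically
#' @param p a `cpoly`.
#' @param vals named numeric vector of variable values.
#' @return A double.
#' @export
poly_eval <- function(p, vals) p_eval_num(p, vals)

#' Terms of a polynomial
#'
#' One row per monomial with its exact rational coefficient, in canonical
#' (lexicographic monomial key) order.
#' @param p a `cpoly`.
#' @return Tibble with columns `term`, `coef_num`, `coef_den`, `coef`.
#' @export
poly_terms <- function(p) {
  tibble::tibble(
    term = vapply(seq_along(p$coefn), function(i) {
      k <- p$keys[i]
      if (k == "") "1" else gsub("\\^1(?=$|\\*)", "", k, perl = TRUE)
    }, character(1)),
    coef_num = p$coefn,
    coef_den = p$coefd,
    coef = p$coefn / p$coefd
  )
}

# monomials whose rational coefficient is negative (with parameters read as
# positive symbols): the candidate destabilising "multiplicative topologies"
p_negative_terms <- function(p) {
  tt <- poly_terms(p)
  tt[tt$coef_num < 0, , drop = FALSE]
}

fmt_coef <- function(n, d) {
  ifelse(d == 1, as.character(n), paste0(n, "/", d))
}

#' @export
format.cpoly <- function(x, ...) {
  if (p_is_zero(x)) return("0")
  parts <- character(length(x$coefn))
  for (i in seq_along(x$coefn)) {
    n <- x$coefn[i]; d <- x$coefd[i]
    mono <- x$keys[i]
    mono <- gsub("\\^1(?=$|\\*)", "", mono, perl = TRUE)
    core <- if (mono == "") fmt_coef(abs(n), d)
            else if (abs(n) == 1 && d == 1) mono
            else paste0(fmt_coef(abs(n), d), "*", mono)
    parts[i] <- if (i == 1) {
      if (n < 0) paste0("-", core) else core
    } else {
      paste0(if (n < 0) " - " else " + ", core)
    }
  }
  paste0(parts, collapse = "")
}

#' @export
print.cpoly <- function(x, ...) {
  cat("<cpoly> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.cpoly <- function(x, ...) format(x)

#' Parse a polynomial from text
#'
#' Understands `+ - * / ^`, integer literals and parentheses; every other
#' name becomes a symbol. Division must be by a rational constant.
#' @param text e.g. `"rho1*rho2*(rho1 + rho2 - 1)"`.
#' @return A `cpoly`.
#' @export
poly_parse <- function(text) {
  expr <- parse(text = text)[[1]]
  env <- new.env(parent = baseenv())
  for (v in all.vars(expr)) assign(v, poly_sym(v), envir = env)
  out <- eval(expr, env)
  as_cpoly(out)
}

# determinant of a square list-matrix of cpoly by cofactor expansion,
# choosing at each level the column with the most exact zeros
p_det <- function(M) {
  k <- nrow(M)
  if (k == 0) return(p_one())
  if (k == 1) return(M[[1, 1]])
  nz <- apply(M, 2, function(col) sum(vapply(col, p_is_zero, logical(1))))
  j <- which.max(nz)
  out <- p_zero()
  for (i in seq_len(k)) {
    e <- M[[i, j]]
    if (p_is_zero(e)) next
    minor <- M[-i, -j, drop = FALSE]
    sgn <- if ((i + j) %% 2 == 0) 1 else -1
    out <- p_add(out, p_scale(p_mul(e, p_det(minor)), sgn))
  }
  out
}

# list-matrix helper
poly_matrix <- function(entries, nrow, ncol) {
  matrix(entries, nrow = nrow, ncol = ncol)
}
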