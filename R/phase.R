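# Stability phase space: the reduced parameter domain partitioned into zones
# by the signs of the Hurwitz determinants. Each zone carries a fixed number
# of unstable roots; a Hopf candidate is a transition from an all-positive
# zone into one where the last two determinants go negative together.

#' Compactifying coordinate transform
#'
#' `zeta = (2/pi) atan(rho)` maps the positive parameter axis `(0, Inf)`
#' monotonically onto `(0, 1)`; [rho_from_zeta()] is its inverse.
#' @param rho,zeta numeric vectors.
#' @export
zeta_from_rho <- function(rho) (2 / pi) * atan(rho)

#' @rdname zeta_from_rho
#' @export
rho_from_zeta <- function(zeta) tan(pi * zeta / 2)

# |coefficients| polynomial for running-magnitude tolerance scales
abs_poly <- function(p) {
  q <- p
  q$coefn <- abs(q$coefn)
  q
}

# sign with exact fallback: v is the double value, scale its magnitude
# estimate, rq_vals the rationalized point for the exact route
sign_with_fallback <- function(p, v, scale, rq_vals) {
  if (abs(v) > 1e-9 * (1 + scale)) return(as.integer(sign(v)))
  ex <- p_eval_rq(p, rq_vals)
  if (is.null(ex)) return(0L)   # exact route overflowed: treat as boundary
  as.integer(sign(ex[1]))
}

fast_routh_k <- function(signs) {
  if (any(signs == 0)) {
    rc <- tryCatch(count_unstable_roots(as.numeric(signs)),
                   error = function(e) NULL)
    if (is.null(rc) || rc$indeterminate) return(NA_integer_)
    return(rc$k)
  }
  ent <- c(1, signs[1], signs[-1] * signs[-length(signs)])
  as.integer(sum(diff(ent) != 0))
}

#' Scan the stability phase space
#'
#' Evaluates every Hurwitz determinant of a reduced topology over a 1D or 2D
#' grid in the compactified coordinates `zeta = (2/pi) atan(rho)`, records
#' the determinant signs and the Routh unstable-root count per point. Grid
#' values are evaluated in double precision; any value within the relative
#' tolerance of zero is re-decided exactly (rational arithmetic at the
#' rationalized grid point), so sign boundaries are not misplaced by
#' roundoff.
#'
#' @param reduced a `reduced_topology`.
#' @param axes one or two parameter names to vary.
#' @param fixed named numeric values (strictly positive) for the remaining
#'   parameters.
#' @param resolution grid points per axis (>= 3).
#' @return A `phase_space_map`: tibble with the grid coordinates, one
#'   `sgn_delta<q>` column per determinant, the sign pattern, and `k`
#'   (`NA` where the first-order analysis is indeterminate). Attributes
#'   carry the axes, fixed values and substituted determinants.
#' @export
scan_phase_space <- function(reduced, axes, fixed = numeric(0),
                             resolution = 201) {
  stopifnot(inherits(reduced, "reduced_topology"), resolution >= 3)
  params <- reduced$params$param
  if (!all(axes %in% params)) stop("unknown axis parameter")
  if (length(axes) < 1 || length(axes) > 2)
    stop("only 1D and 2D scans are supported")
  rest <- setdiff(params, axes)
  missing_fixed <- setdiff(rest, names(fixed))
  if (length(missing_fixed))
    stop("fix the non-axis parameters: ", paste(missing_fixed, collapse = ", "))
  if (any(fixed[rest] <= 0)) stop("fixed parameter values must be positive")

  subs <- lapply(fixed[rest], function(v) {
    r <- rationalize(v)
    poly_const(r[1], r[2])
  })
  names(subs) <- rest
  deltas <- lapply(reduced$hurwitz$deltas, p_subst, subs = subs)
  absd <- lapply(deltas, abs_poly)
  nq <- length(deltas)

  zgrid <- seq_len(resolution) / (resolution + 1)
  rho <- rho_from_zeta(zgrid)
  rho_rq <- lapply(rho, rationalize, max_den = 1e4)

  pts <- if (length(axes) == 2)
    expand.grid(i1 = seq_len(resolution), i2 = seq_len(resolution))
  else data.frame(i1 = seq_len(resolution))

  sgn_mat <- matrix(0L, nrow = nrow(pts), ncol = nq)
  kvec <- integer(nrow(pts))
  for (r in seq_len(nrow(pts))) {
    vals <- stats::setNames(rho[pts$i1[r]], axes[1])
    rqv <- stats::setNames(list(rho_rq[[pts$i1[r]]]), axes[1])
    if (length(axes) == 2) {
      vals[axes[2]] <- rho[pts$i2[r]]
      rqv[[axes[2]]] <- rho_rq[[pts$i2[r]]]
    }
    s <- integer(nq)
    for (q in seq_len(nq)) {
      v <- p_eval_num(deltas[[q]], vals)
      sc <- p_eval_num(absd[[q]], vals)
      s[q] <- sign_with_fallback(deltas[[q]], v, sc, rqv)
    }
    sgn_mat[r, ] <- s
    kvec[r] <- fast_routh_k(s)
  }

  out <- tibble::as_tibble(pts)
  out[[paste0("zeta_", axes[1])]] <- zgrid[pts$i1]
  out[[axes[1]]] <- rho[pts$i1]
  if (length(axes) == 2) {
    out[[paste0("zeta_", axes[2])]] <- zgrid[pts$i2]
    out[[axes[2]]] <- rho[pts$i2]
  }
  for (q in seq_len(nq)) out[[paste0("sgn_delta", q)]] <- sgn_mat[, q]
  out$pattern <- apply(sgn_mat, 1, function(s)
    paste(c("-", "0", "+")[s + 2], collapse = ""))
  out$k <- kvec
  structure(out, axes = axes, fixed = fixed, deltas = deltas,
            resolution = resolution,
            class = c("phase_space_map", class(out)))
}

#' Zone and Hopf-candidate classification
#'
#' Zones are 4-connected components of constant determinant-sign pattern.
#' A Hopf-candidate cell has `Delta_{n-1} < 0`, `Delta_n < 0`, all earlier
#' determinants positive, and an all-positive (stable) 4-neighbour: crossing
#' that boundary creates a purely imaginary pair.
#'
#' @param map a `phase_space_map` from [scan_phase_space()].
#' @return The map with `zone` (integer) and `hopf` (logical) columns; a
#'   `zone_table` attribute summarises `k` per zone.
#' @export
classify_zones <- function(map) {
  axes <- attr(map, "axes")
  res <- attr(map, "resolution")
  n1 <- res
  n2 <- if (length(axes) == 2) res else 1
  idx <- function(i1, i2) (i2 - 1) * n1 + i1
  ord <- order(if (length(axes) == 2) map$i2 else rep(1, nrow(map)), map$i1)
  map <- map[ord, ]

  pattern <- map$pattern
  zone <- rep(NA_integer_, nrow(map))
  zid <- 0
  for (start in seq_len(nrow(map))) {
    if (!is.na(zone[start])) next
    zid <- zid + 1
    queue <- start
    zone[start] <- zid
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      i1 <- ((cur - 1) %% n1) + 1
      i2 <- ((cur - 1) %/% n1) + 1
      for (nb in list(c(i1 - 1, i2), c(i1 + 1, i2),
                      c(i1, i2 - 1), c(i1, i2 + 1))) {
        if (nb[1] < 1 || nb[1] > n1 || nb[2] < 1 || nb[2] > n2) next
        j <- idx(nb[1], nb[2])
        if (is.na(zone[j]) && pattern[j] == pattern[cur]) {
          zone[j] <- zid
          queue <- c(queue, j)
        }
      }
    }
  }
  map$zone <- zone

  nq <- sum(grepl("^sgn_delta", names(map)))
  sgn <- as.matrix(map[paste0("sgn_delta", seq_len(nq))])
  earlier_pos <- if (nq > 2)
    apply(sgn[, seq_len(nq - 2), drop = FALSE] > 0, 1, all)
  else rep(TRUE, nrow(map))
  is_hopf_pattern <- if (nq >= 2) {
    (sgn[, nq] < 0) & (sgn[, nq - 1] < 0) & earlier_pos
  } else rep(FALSE, nrow(map))
  all_pos <- apply(sgn > 0, 1, all)
  hopf <- rep(FALSE, nrow(map))
  for (cur in which(is_hopf_pattern)) {
    i1 <- ((cur - 1) %% n1) + 1
    i2 <- ((cur - 1) %/% n1) + 1
    for (nb in list(c(i1 - 1, i2), c(i1 + 1, i2),
                    c(i1, i2 - 1), c(i1, i2 + 1))) {
      if (nb[1] < 1 || nb[1] > n1 || nb[2] < 1 || nb[2] > n2) next
      if (all_pos[idx(nb[1], nb[2])]) { hopf[cur] <- TRUE; break }
    }
  }
  map$hopf <- hopf

  zt <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(map), zone),
                         pattern = dplyr::first(pattern),
                         k = dplyr::first(k),
                         n_cells = dplyr::n(),
                         any_hopf = any(hopf), .groups = "drop")
  attr(map, "zone_table") <- zt
  map
}

#' @export
print.phase_space_map <- function(x, ...) {
  axes <- attr(x, "axes")
  cat("<phase_space_map> ", nrow(x), " grid points over ",
      paste(axes, collapse = " x "), "\n", sep = "")
  zt <- attr(x, "zone_table")
  if (!is.null(zt)) {
    cat("zones:\n")
    print(zt)
  } else {
    print(tibble::as_tibble(x))
  }
  invisible(x)
}

#' Evaluate reduced determinants at a parameter point, exactly
#'
#' Substitutes rational parameter values into the reduced Hurwitz
#' determinants and returns exact signs and the Routh count.
#'
#' @param reduced a `reduced_topology`.
#' @param values named numeric (rationalized exactly) or named list of
#'   `c(num, den)` pairs covering all reduced parameters.
#' @return List: `deltas` (numeric), `signs`, `routh` (a `routh_count`).
#' @export
evaluate_reduced <- function(reduced, values) {
  if (!is.list(values)) values <- lapply(values, function(v) rationalize(v))
  vars <- unique(unlist(lapply(reduced$hurwitz$deltas, poly_vars)))
  if (!all(vars %in% names(values)))
    stop("values must cover every reduced parameter")
  subs <- lapply(values, function(r) poly_const(r[1], r[2]))
  dl <- tryCatch(lapply(reduced$hurwitz$deltas, p_subst, subs = subs),
                 error = function(e) NULL)
  if (!is.null(dl)) {
    num <- vapply(dl, p_to_num, numeric(1))
    signs <- vapply(dl, p_sign, integer(1))
    return(list(deltas = num, signs = signs, exact = TRUE,
                routh = count_unstable_roots(dl)))
  }
  # the exact route would exceed 2^53: fall back to doubles with the
  # running-magnitude tolerance
  vnum <- vapply(values, function(r) r[1] / r[2], numeric(1))
  num <- vapply(reduced$hurwitz$deltas, p_eval_num, numeric(1), vals = vnum)
  list(deltas = num, signs = delta_signs(num), exact = FALSE,
       routh = count_unstable_roots(num))
}

#' Steady-state locus of a classical fixture
#'
#' Maps explicit model constants onto the reduced parameters via the
#' fixture's closed-form steady-state projection.
#'
#' @param fixture a `fixture_bundle` (or fixture name).
#' @param constants named list of model constants (defaults from the
#'   bundle).
#' @return Tibble with `param`, `value`, `zeta`, `boundary` (TRUE when the
#'   value sits on the closure of the positive orthant rather than inside).
#' @export
map_steady_state <- function(fixture, constants = list()) {
  if (is.character(fixture)) fixture <- make_classical_network(fixture, constants)
  if (is.null(fixture$steady_state_map))
    stop("fixture has no closed-form steady-state mapping: ", fixture$name)
  cs <- merge_constants(fixture$constants, constants)
  v <- fixture$steady_state_map(cs)
  if (any(v < 0)) stop("constants map outside the positivity assumptions")
  tibble::tibble(param = names(v), value = unname(v),
                 zeta = zeta_from_rho(unname(v)),
                 boundary = unname(v) == 0)
}

#' Plot a stability phase space map
#'
#' Mirrors the figure convention of the field: zones where `Delta_1` is
#' negative shaded black, `Delta_2` red, `Delta_3` blue (semi-transparent,
#' so overlaps compose); Hopf-candidate cells outlined in orange.
#'
#' @param object a classified `phase_space_map`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot phase_space_map
#' @export
autoplot.phase_space_map <- function(object, ...) {
  axes <- attr(object, "axes")
  if (length(axes) != 2)
    stop("autoplot supports 2D maps; plot 1D scans directly")
  zx <- paste0("zeta_", axes[1]); zy <- paste0("zeta_", axes[2])
  df <- tibble::as_tibble(object)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[zx]], y = .data[[zy]])) +
    ggplot2::geom_raster(fill = "white")
  cols <- c("black", "red", "blue")
  nq <- sum(grepl("^sgn_delta", names(df)))
  for (q in seq_len(min(3, nq))) {
    sub <- df[df[[paste0("sgn_delta", q)]] < 0, ]
    if (nrow(sub))
      gg <- gg + ggplot2::geom_raster(data = sub, fill = cols[q],
                                      alpha = 0.35)
  }
  if ("hopf" %in% names(df) && any(df$hopf)) {
    gg <- gg + ggplot2::geom_tile(data = df[df$hopf, ], fill = NA,
                                  colour = "orange", linewidth = 0.2)
  }
  gg + ggplot2::coord_equal() +
    ggplot2::labs(x = paste0("zeta(", axes[1], ")"),
                  y = paste0("zeta(", axes[2], ")"),
                  title = "Stability phase space") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Export a phase-space map as CSV
#' @param map a `phase_space_map`.
#' @param path output file.
#' @export
export_phase_space <- function(map, path) {
  utils::write.csv(tibble::as_tibble(map), path, row.names = FALSE)
  invisible(path)
}
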