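# Parameter reduction of the influence topology:
#   1. stoichiometric scaling  - one stoichiometric edge per reaction is
#      rescaled to +/-1, the factor moving into that reaction's Jacobian
#      edges (a pure redefinition of the reaction function);
#   2. cycle compaction        - edges sharing an identical cycle-membership
#      "barcode" always appear together in every minor, so each such group
#      collapses to a single parameter;
#   3. temporal scaling        - one Jacobian-bearing group is scaled to
#      +/-1 by rescaling time, which divides every eigenvalue by beta > 0
#      and so never changes stability.
# The surviving parameters (rho_i for Jacobian-bearing groups, sigma_j for
# purely stoichiometric ones) span the stability phase space of dimension
# d = (S - m) + J - c - 1.

# --- magnitude ratios: products/quotients of positive symbols and rationals
mag_new <- function(syms_num = character(0), syms_den = character(0),
                    q = c(1, 1)) {
  # cancel common symbols (multiset difference)
  for (s in unique(syms_num)) {
    k <- min(sum(syms_num == s), sum(syms_den == s))
    if (k > 0) {
      syms_num <- syms_num[-which(syms_num == s)[seq_len(k)]]
      syms_den <- syms_den[-which(syms_den == s)[seq_len(k)]]
    }
  }
  list(syms_num = sort(syms_num), syms_den = sort(syms_den), q = rq(q[1], q[2]))
}

mag_one <- function() mag_new()
mag_from_edge <- function(row) {
  if (!is.na(row$w_sym)) mag_new(syms_num = row$w_sym)
  else mag_new(q = c(row$w_num, row$w_den))
}
mag_mul <- function(a, b) mag_new(c(a$syms_num, b$syms_num),
                                  c(a$syms_den, b$syms_den),
                                  rq_mul(a$q, b$q))
mag_div <- function(a, b) mag_new(c(a$syms_num, b$syms_den),
                                  c(a$syms_den, b$syms_num),
                                  rq(a$q[1] * b$q[2], a$q[2] * b$q[1]))
mag_has_sym <- function(a) length(a$syms_num) + length(a$syms_den) > 0
mag_is_unit <- function(a) !mag_has_sym(a) && a$q[1] == 1 && a$q[2] == 1
mag_eval <- function(a, vals) {
  v <- a$q[1] / a$q[2]
  for (s in a$syms_num) {
    if (is.na(vals[s])) stop("missing value for symbol: ", s)
    v <- v * unname(vals[s])
  }
  for (s in a$syms_den) {
    if (is.na(vals[s])) stop("missing value for symbol: ", s)
    v <- v / unname(vals[s])
  }
  v
}
mag_format <- function(a) {
  num <- c(if (a$q[1] != 1 || length(a$syms_num) == 0)
    fmt_coef(a$q[1], 1) else NULL, a$syms_num)
  out <- paste(num, collapse = "*")
  den <- c(if (a$q[2] != 1) as.character(a$q[2]) else NULL, a$syms_den)
  if (length(den)) out <- paste0(out, "/", paste(den, collapse = "/"))
  out
}

# --- stoichiometric scaling -------------------------------------------------

scalable_reactions <- function(topo) {
  topo$reactions$id[!topo$reactions$is_orphan]
}

# number of symbolic parameter groups for a given per-reaction unit choice
n_param_groups <- function(topo, cycles, choice) {
  mags <- scaled_edge_mags(topo, choice)
  bc <- edge_barcodes(topo, cycles)
  if (length(bc) == 0) return(0L)
  keys <- names(bc)
  groups <- split(keys, vapply(keys, function(k) bc[[k]], character(1)))
  sum(vapply(groups, function(ks) {
    m <- Reduce(mag_mul, mags[ks], mag_one())
    mag_has_sym(m)
  }, logical(1)))
}

# per-edge scaled magnitudes, named by canonical edge key
scaled_edge_mags <- function(topo, choice) {
  alpha <- list()
  for (rid in scalable_reactions(topo)) {
    se <- topo$stoich[topo$stoich$reaction == rid, ]
    pick <- choice[[rid]]
    row <- se[se$species == pick, ]
    if (nrow(row) != 1) stop("invalid scaling choice for reaction ", rid)
    alpha[[rid]] <- mag_from_edge(row)
  }
  mags <- list()
  for (i in seq_len(nrow(topo$jac))) {
    e <- topo$jac[i, ]
    mags[[paste0("J:", e$species, ":", e$reaction)]] <-
      mag_mul(mag_from_edge(e), alpha[[e$reaction]])
  }
  for (i in seq_len(nrow(topo$stoich))) {
    e <- topo$stoich[i, ]
    if (!e$reaction %in% names(alpha)) next
    mags[[paste0("S:", e$reaction, ":", e$species)]] <-
      mag_div(mag_from_edge(e), alpha[[e$reaction]])
  }
  mags
}

# cycle-membership bit strings for every edge on at least one cycle
edge_barcodes <- function(topo, cycles) {
  nc <- nrow(cycles)
  bc <- list()
  for (ci in seq_len(nc)) {
    for (k in cycles$edge_keys[[ci]]) {
      if (is.null(bc[[k]])) bc[[k]] <- rep(0L, nc)
      bc[[k]][ci] <- 1L
    }
  }
  lapply(bc, function(v) paste(v, collapse = ""))
}

#' Stoichiometric scaling
#'
#' Rescales each (non-orphan) reaction so that one chosen stoichiometric
#' edge has magnitude 1, multiplying that reaction's Jacobian edges by the
#' absorbed factor. When `choice` is `NULL` every per-reaction selection is
#' tried and the one minimising the final reduced dimensionality (after
#' cycle compaction) is kept, ties broken lexicographically by the chosen
#' species ids. The transformation is a pure redefinition of the reaction
#' functions and leaves every transition-matrix entry, hence the spectrum,
#' unchanged.
#'
#' @param topo fixed-sign `influence_topology`.
#' @param choice optional named character vector: reaction id to the species
#'   id of the stoichiometric edge scaled to unit.
#' @param max_search guard on the number of selections tried.
#' @return A `scaled_topology`: the base topology plus per-edge scaled
#'   magnitudes and the scaling record.
#' @export
stoichiometric_scaling <- function(topo, choice = NULL, max_search = 1e5) {
  validate_topology(topo)
  cycles <- enumerate_cycles(topo)
  rids <- scalable_reactions(topo)
  opts <- lapply(rids, function(rid)
    sort(topo$stoich$species[topo$stoich$reaction == rid]))
  names(opts) <- rids
  if (is.null(choice)) {
    total <- prod(vapply(opts, length, numeric(1)))
    if (total > max_search)
      stop("scaling choice space exceeds ", max_search, " combinations")
    grid <- expand.grid(rev(opts), stringsAsFactors = FALSE)
    grid <- grid[, rev(seq_along(opts)), drop = FALSE]
    grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
    best <- NULL; best_d <- Inf
    for (i in seq_len(nrow(grid))) {
      ch <- as.list(grid[i, , drop = FALSE])
      names(ch) <- rids
      d <- n_param_groups(topo, cycles, ch)
      if (d < best_d) { best_d <- d; best <- ch }
    }
    choice <- unlist(best)
  } else {
    choice <- choice[rids]
    if (any(is.na(choice))) stop("scaling choice must cover every reaction")
  }
  mags <- scaled_edge_mags(topo, as.list(choice))
  alpha <- lapply(stats::setNames(rids, rids), function(rid) {
    row <- topo$stoich[topo$stoich$reaction == rid &
                         topo$stoich$species == choice[[rid]], ]
    mag_from_edge(row)
  })
  structure(list(topo = topo, cycles = cycles, choice = choice,
                 alpha = alpha, mags = mags),
            class = "scaled_topology")
}

#' @export
print.scaled_topology <- function(x, ...) {
  cat("<scaled_topology> unit stoichiometric edge per reaction:\n")
  for (rid in names(x$choice))
    cat("  ", rid, " -> ", x$choice[[rid]], "  (alpha = ",
        mag_format(x$alpha[[rid]]), ")\n", sep = "")
  invisible(x)
}

# --- cycle compaction -------------------------------------------------------

#' Cycle compaction
#'
#' Groups every cycle edge by its cycle-membership barcode: two edges share
#' a group exactly when they lie in the same set of bipartite cycles, and
#' then they appear in every minor only through their product, which
#' collapses to a single parameter. Groups whose product carries no symbol
#' contribute a fixed rational; composite symbolic groups are named `q0,
#' q1, ...` in barcode order, single-symbol groups keep their symbol.
#'
#' @param scaled a `scaled_topology` (or a fixed-sign `influence_topology`,
#'   scaled with default choices first).
#' @return A `compaction_result`: `groups` tibble (`group`, `barcode`,
#'   `edges`, `magnitude`, `sign`, `z` Jacobian edges, `constant`), the
#'   cycle table, per-cycle group memberships, and `c`, the number of
#'   parameter dimensions removed.
#' @export
cycle_compaction <- function(scaled) {
  if (inherits(scaled, "influence_topology"))
    scaled <- stoichiometric_scaling(scaled)
  stopifnot(inherits(scaled, "scaled_topology"))
  topo <- scaled$topo
  cycles <- scaled$cycles
  nc <- nrow(cycles)
  ct <- topo_counts(topo)
  n_params_before <- (ct$S - ct$m) + ct$J
  if (nc == 0) {
    groups <- tibble::tibble(group = character(), barcode = character(),
                             edges = list(), magnitude = list(),
                             sign = integer(), z = integer(),
                             constant = logical())
    return(structure(list(scaled = scaled, cycles = cycles, groups = groups,
                          c = 0L, n_params_before = n_params_before),
                     class = "compaction_result"))
  }
  bc <- edge_barcodes(topo, cycles)
  keys <- names(bc)
  codes <- vapply(keys, function(k) bc[[k]], character(1))
  split_keys <- split(keys, codes)
  ord <- order(names(split_keys))
  split_keys <- split_keys[ord]

  sign_of <- function(key) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    if (parts[1] == "J") {
      topo$jac$sign[topo$jac$species == parts[2] &
                      topo$jac$reaction == parts[3]]
    } else {
      topo$stoich$sign[topo$stoich$reaction == parts[2] &
                         topo$stoich$species == parts[3]]
    }
  }
  rows <- purrr::map(seq_along(split_keys), function(i) {
    ks <- sort(split_keys[[i]])
    m <- Reduce(mag_mul, scaled$mags[ks], mag_one())
    sgn <- prod(vapply(ks, sign_of, integer(1)))
    z <- sum(startsWith(ks, "J:"))
    tibble::tibble(barcode = names(split_keys)[i], edges = list(ks),
                   magnitude = list(m), sign = as.integer(sgn),
                   z = as.integer(z), constant = !mag_has_sym(m))
  })
  groups <- dplyr::bind_rows(rows)
  # names: keep a lone symbol's own name, else q0, q1, ... in barcode order
  qi <- -1
  groups$group <- vapply(seq_len(nrow(groups)), function(i) {
    m <- groups$magnitude[[i]]
    if (groups$constant[i]) return(paste0("const", i))
    if (length(m$syms_num) == 1 && length(m$syms_den) == 0 &&
        m$q[1] == 1 && m$q[2] == 1) return(m$syms_num)
    qi <<- qi + 1
    paste0("q", qi)
  }, character(1))

  n_param_groups <- sum(!groups$constant)
  structure(list(scaled = scaled, cycles = cycles, groups = groups,
                 c = as.integer(n_params_before - n_param_groups),
                 n_params_before = n_params_before),
            class = "compaction_result")
}

#' @export
print.compaction_result <- function(x, ...) {
  cat("<compaction_result> ", nrow(x$groups), " overlap group(s), c = ",
      x$c, " dimension(s) removed\n", sep = "")
  for (i in seq_len(nrow(x$groups))) {
    g <- x$groups[i, ]
    cat("  ", format(g$group, width = 8), " barcode ", g$barcode,
        "  sign ", if (g$sign > 0) "+" else "-", "  ",
        mag_format(g$magnitude[[1]]), "\n", sep = "")
  }
  invisible(x)
}

# --- temporal scaling -------------------------------------------------------

#' Temporal scaling
#'
#' Chooses one Jacobian-bearing compaction group as the unit of time:
#' `beta = |group magnitude|^(1/z)` with `z` the number of Jacobian edges in
#' the group. Every other Jacobian-bearing group is divided by the matching
#' power of `beta` and becomes a strictly positive parameter `rho_i`; purely
#' stoichiometric groups survive as `sigma_j`. Eigenvalues divide by
#' `beta > 0`, so unstable-root counts are untouched.
#'
#' The default unit is the Jacobian-bearing group with the lexicographically
#' smallest barcode; pass `unit` (a group name, or a symbol it contains) to
#' override.
#'
#' @param compacted a `compaction_result`.
#' @param unit optional unit group.
#' @return A `reduced_topology`: parameter table (`param`, `kind`, `sign`,
#'   `z`, `definition`), `beta` definition, reduced cycle weights, the
#'   reduced `minor_set` and `hurwitz_result`, and the final dimensionality
#'   `d`.
#' @export
temporal_scaling <- function(compacted, unit = NULL) {
  stopifnot(inherits(compacted, "compaction_result"))
  g <- compacted$groups
  jac_groups <- which(!g$constant & g$z >= 1)
  if (length(jac_groups) == 0)
    stop("no Jacobian-bearing parameter group: temporal scaling impossible")
  if (is.null(unit)) {
    ui <- jac_groups[which.min(g$barcode[jac_groups])]
  } else {
    ui <- which(g$group == unit |
                  vapply(g$magnitude, function(m)
                    unit %in% c(m$syms_num, m$syms_den), logical(1)))
    if (length(ui) != 1) stop("unit group not found or ambiguous: ", unit)
    if (g$constant[ui] || g$z[ui] < 1)
      stop("unit group has no Jacobian content")
  }
  z0 <- g$z[ui]
  beta <- list(mag = g$magnitude[[ui]], z = z0)

  others <- setdiff(which(!g$constant), ui)
  # deterministic order: smallest member symbol of each group
  key <- vapply(others, function(i) {
    m <- g$magnitude[[i]]
    s <- sort(c(m$syms_num, m$syms_den))
    s[1]
  }, character(1))
  others <- others[order(key)]
  ri <- 0; si <- 0
  params <- purrr::map(others, function(i) {
    m <- g$magnitude[[i]]
    if (g$z[i] >= 1) {
      ri <<- ri + 1
      nm <- if (length(m$syms_num) == 1 && length(m$syms_den) == 0 &&
                grepl("^r[0-9]+$", m$syms_num))
        sub("^r", "rho", m$syms_num) else paste0("rho", ri)
      kind <- "rho"
    } else {
      si <<- si + 1
      nm <- if (length(m$syms_num) == 1 && length(m$syms_den) == 0)
        m$syms_num else paste0("sigma", si)
      kind <- "sigma"
    }
    tibble::tibble(param = nm, kind = kind, group = g$group[i],
                   sign = g$sign[i], z = g$z[i], magnitude = list(m))
  })
  params <- if (length(params)) dplyr::bind_rows(params) else
    tibble::tibble(param = character(), kind = character(),
                   group = character(), sign = integer(), z = integer(),
                   magnitude = list())
  if (anyDuplicated(params$param)) {
    params$param <- make.unique(params$param, sep = "_")
  }

  # reduced weight of each cycle as a polynomial over the surviving params
  group_term <- function(i) {
    if (i == ui) return(poly_const(g$sign[i]))
    if (g$constant[i]) {
      m <- g$magnitude[[i]]
      return(poly_const(g$sign[i] * m$q[1], m$q[2]))
    }
    j <- match(g$group[i], params$group)
    p_scale(poly_sym(params$param[j]), g$sign[i])
  }
  barcode_bit <- function(code, ci) substr(code, ci, ci) == "1"
  cycles <- compacted$cycles
  red_weights <- lapply(seq_len(nrow(cycles)), function(ci) {
    w <- p_one()
    for (i in seq_len(nrow(g)))
      if (barcode_bit(g$barcode[i], ci)) w <- p_mul(w, group_term(i))
    w
  })
  red_cycles <- cycles
  red_cycles$weight <- red_weights
  red_cycles$sign <- vapply(red_weights, function(w) {
    if (p_is_zero(w)) 0L else as.integer(sign(w$coefn[1]))
  }, integer(1))

  n <- sum(!compacted$scaled$topo$species$clamped)
  minors <- principal_minors(red_cycles, n = n)
  hw <- hurwitz_determinants(charpoly_coefficients(minors$b))

  structure(list(
    compacted = compacted, unit = g$group[ui], unit_sign = g$sign[ui],
    beta = beta, params = params,
    d = nrow(params), cycles = red_cycles,
    minors = minors, hurwitz = hw,
    n = n
  ), class = "reduced_topology")
}

#' @export
print.reduced_topology <- function(x, ...) {
  cat("<reduced_topology> d = ", x$d, " surviving parameter(s); unit ",
      x$unit, " (sign ", if (x$unit_sign > 0) "+" else "-",
      "), beta = |", mag_format(x$beta$mag), "|",
      if (x$beta$z > 1) paste0("^(1/", x$beta$z, ")"), "\n", sep = "")
  for (i in seq_len(nrow(x$params))) {
    p <- x$params[i, ]
    denom <- if (p$kind == "rho")
      paste0(" / beta", if (p$z > 1) paste0("^", p$z)) else ""
    cat("  ", format(p$param, width = 8), " = ",
        if (p$sign < 0) "-", mag_format(p$magnitude[[1]]), denom,
        "\n", sep = "")
  }
  invisible(x)
}

#' Numeric values of the reduced parameters
#'
#' Maps an assignment of the original edge-weight symbols to the surviving
#' reduced parameters (and `beta`), for cross-checking that reduction
#' preserves unstable-root counts.
#'
#' @param reduced a `reduced_topology`.
#' @param values named numeric vector for the original symbols.
#' @return Named numeric vector of reduced parameter values plus `.beta`.
#' @export
reduce_values <- function(reduced, values) {
  beta <- mag_eval(reduced$beta$mag, values)^(1 / reduced$beta$z)
  out <- stats::setNames(numeric(nrow(reduced$params)), reduced$params$param)
  for (i in seq_len(nrow(reduced$params))) {
    p <- reduced$params[i, ]
    v <- mag_eval(p$magnitude[[1]], values)
    out[p$param] <- v / beta^p$z
  }
  c(out, .beta = beta)
}

#' Reduced dimensionality of a topology
#'
#' `d = (S - m) + J - c - 1` under the best stoichiometric-scaling choice:
#' the number of strictly positive parameters spanning the stability phase
#' space after all three reductions.
#'
#' @param topo fixed-sign `influence_topology`.
#' @return Integer dimensionality.
#' @export
reduced_dimension <- function(topo) {
  cmp <- cycle_compaction(stoichiometric_scaling(topo))
  n_groups <- sum(!cmp$groups$constant)
  if (n_groups == 0) return(0L)
  as.integer(n_groups - 1L)
}

#' Full reduction pipeline
#'
#' Convenience chain: stoichiometric scaling, cycle compaction, temporal
#' scaling.
#'
#' @param topo fixed-sign `influence_topology`.
#' @param choice optional stoichiometric scaling choice.
#' @param unit optional temporal unit group (group name or member symbol).
#' @return A `reduced_topology`.
#' @export
reduce_topology <- function(topo, choice = NULL, unit = NULL) {
  temporal_scaling(cycle_compaction(stoichiometric_scaling(topo, choice)),
                   unit = unit)
}

# --- exchange symmetries ----------------------------------------------------

all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    rest <- all_permutations(v[-i])
    for (r in rest) out[[length(out) + 1]] <- c(v[i], r)
  }
  out
}

#' Detect exchange symmetries of the principal minors
#'
#' Finds the parameter permutations under which every `b_q` is invariant
#' (verified by exact substitution); such topological symmetries justify
#' aggregate parameters `Psi` (e.g. the sum of an exchangeable pair).
#' Full permutation search is done for up to 6 parameters; beyond that only
#' transpositions are tested.
#'
#' @param minors a `minor_set` over reduced parameters, or a
#'   `reduced_topology`.
#' @param params parameters to permute; defaults to all variables in the
#'   minors.
#' @return A `symmetry_report`: `permutations` (list of named character
#'   vectors, identity excluded), `psi_candidates` (character suggestions).
#' @export
detect_exchange_symmetries <- function(minors, params = NULL) {
  if (inherits(minors, "reduced_topology")) minors <- minors$minors
  b <- if (inherits(minors, "minor_set")) minors$b else minors
  if (is.null(params))
    params <- sort(unique(unlist(lapply(b, poly_vars))))
  perms <- if (length(params) <= 6) {
    all_permutations(params)
  } else {
    out <- list()
    for (i in seq_along(params)) for (j in seq_along(params)) if (i < j) {
      p <- params
      p[c(i, j)] <- p[c(j, i)]
      out[[length(out) + 1]] <- p
    }
    out
  }
  hits <- list()
  for (p in perms) {
    if (identical(p, params)) next
    subs <- stats::setNames(lapply(p, poly_sym), params)
    ok <- all(vapply(b, function(bq)
      p_equal(as_cpoly(bq), p_subst(as_cpoly(bq), subs)), logical(1)))
    if (ok) hits[[length(hits) + 1]] <- stats::setNames(p, params)
  }
  psi <- character(0)
  moved <- unique(unlist(lapply(hits, function(p)
    names(p)[p != names(p)])))
  if (length(moved) >= 2) {
    # orbit of the symmetry group on the parameters
    orbit <- sort(moved)
    psi <- paste0("Psi = ", paste(orbit, collapse = " + "))
  }
  structure(list(permutations = hits, psi_candidates = psi,
                 params = params), class = "symmetry_report")
}

#' @export
print.symmetry_report <- function(x, ...) {
  cat("<symmetry_report> ", length(x$permutations),
      " non-identity symmetry permutation(s)\n", sep = "")
  for (p in x$permutations)
    cat("  ", paste(names(p), "->", p, collapse = ", "), "\n", sep = "")
  for (s in x$psi_candidates) cat("  candidate aggregate: ", s, "\n", sep = "")
  invisible(x)
}

#' Reduction trace report
#'
#' The chosen stoichiometric scalings, the edge-to-barcode table, and the
#' reduced parameter definitions, as a tidy tibble (optionally CSV).
#'
#' @param reduced a `reduced_topology`.
#' @param path optional CSV path.
#' @return Tibble with columns `section`, `item`, `value`.
#' @export
reduction_trace <- function(reduced, path = NULL) {
  sc <- reduced$compacted$scaled
  rows <- dplyr::bind_rows(
    tibble::tibble(section = "stoichiometric_scaling",
                   item = names(sc$choice),
                   value = paste0("unit edge -> ", unlist(sc$choice))),
    purrr::map_dfr(seq_len(nrow(reduced$compacted$groups)), function(i) {
      grp <- reduced$compacted$groups[i, ]
      tibble::tibble(section = "compaction_group", item = grp$group,
                     value = paste0("barcode ", grp$barcode, "; edges ",
                                    paste(grp$edges[[1]], collapse = " "),
                                    "; product ",
                                    if (grp$sign < 0) "-" else "+",
                                    mag_format(grp$magnitude[[1]])))
    }),
    tibble::tibble(section = "temporal_scaling", item = reduced$unit,
                   value = paste0("beta = |", mag_format(reduced$beta$mag),
                                  "|^(1/", reduced$beta$z, ")")),
    purrr::map_dfr(seq_len(nrow(reduced$params)), function(i) {
      p <- reduced$params[i, ]
      tibble::tibble(section = "parameter", item = p$param,
                     value = paste0(if (p$sign < 0) "-" else "+",
                                    mag_format(p$magnitude[[1]]),
                                    if (p$kind == "rho")
                                      paste0(" / beta^", p$z) else ""))
    })
  )
  if (!is.null(path)) utils::write.csv(rows, path, row.names = FALSE)
  rows
}
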