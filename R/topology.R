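# The influence topology: a signed directed bipartite graph with species and
# reaction nodes. Species -> reaction edges carry the reaction monotonicities
# (Jacobian signs, magnitudes r_i at the steady state); reaction -> species
# edges carry the stoichiometric signs and magnitudes. This is the directed
# species-reaction (DSR) graph of chemical reaction network theory.

sign_chr_to_int <- function(s) {
  switch(s, "+" = 1L, "-" = -1L, "?" = NA_integer_,
         stop("invalid sign: ", s))
}

# parse "+", "-", "?", "+r1", "-r1", "r1", "+2", "-1/2", numeric
# into list(sign, w_num, w_den, w_sym); `default_sym` supplies a fresh
# symbol when no magnitude is given and default_unit is FALSE
parse_weight <- function(x, default_sym = NULL, default_unit = FALSE) {
  if (is.numeric(x)) {
    if (x == 0) stop("edge weight must be nonzero")
    r <- rationalize(abs(x))
    return(list(sign = as.integer(sign(x)), w_num = r[1], w_den = r[2],
                w_sym = NA_character_))
  }
  x <- trimws(as.character(x))
  sgn <- NA_integer_
  if (grepl("^[+?-]", x)) {
    sgn <- sign_chr_to_int(substr(x, 1, 1))
    x <- trimws(substring(x, 2))
  } else {
    sgn <- 1L
  }
  if (!nzchar(x)) {
    if (default_unit)
      return(list(sign = sgn, w_num = 1, w_den = 1, w_sym = NA_character_))
    return(list(sign = sgn, w_num = NA_real_, w_den = NA_real_,
                w_sym = default_sym %||% NA_character_))
  }
  if (grepl("^[0-9]+(/[0-9]+)?$", x)) {
    parts <- strsplit(x, "/", fixed = TRUE)[[1]]
    n <- as.numeric(parts[1]); d <- if (length(parts) > 1) as.numeric(parts[2]) else 1
    if (n == 0) stop("edge weight must be nonzero")
    r <- rq(n, d)
    return(list(sign = sgn, w_num = r[1], w_den = r[2], w_sym = NA_character_))
  }
  if (!grepl("^[A-Za-z][A-Za-z0-9_.]*$", x)) stop("invalid edge weight: ", x)
  list(sign = sgn, w_num = NA_real_, w_den = NA_real_, w_sym = x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build an influence topology
#'
#' Constructs the signed directed bipartite species-reaction graph from a
#' network description. Each reaction lists its signed monotonic dependencies
#' on species (Jacobian edges, species to reaction) and its signed
#' stoichiometric outputs (reaction to species).
#'
#' Signs are `"+"`, `"-"` or `"?"` (unknown monotonicity; downstream cycle
#' algebra refuses unknown signs, expand with [expand_sign_assignments()]
#' first). A magnitude may follow the sign: a symbol name (`"+sigma1"`), or a
#' rational (`"-1/2"`, or a plain number). A bare sign on a Jacobian edge
#' gets a fresh positive symbol (`r1`, `r2`, ... in declaration order) so
#' symbolic minors stay fully general; a bare sign on a stoichiometric edge
#' means magnitude 1.
#'
#' @param reactions named list; each element has `inputs` (named signs,
#'   possibly empty for an orphan reaction) and `outputs` (named signed
#'   weights, at least one).
#' @param species character vector of species ids; defaults to every species
#'   mentioned by the reactions, in order of appearance.
#' @param clamped character vector of clamped (buffered) species ids.
#' @return An `influence_topology` object: tibbles `species`, `reactions`,
#'   `jac`, `stoich`.
#' @examples
#' build_topology(list(
#'   v1 = list(inputs = c(x1 = "+r1"), outputs = c(x1 = "-1"))
#' ))
#' @export
build_topology <- function(reactions, species = NULL, clamped = character()) {
  if (length(reactions) == 0) stop("at least one reaction is required")
  if (is.null(names(reactions)) || any(!nzchar(names(reactions))))
    stop("reactions must be named")
  if (anyDuplicated(names(reactions))) stop("duplicate reaction ids")

  mentioned <- unique(unlist(lapply(reactions, function(r)
    c(names(r$inputs), names(r$outputs)))))
  if (is.null(species)) species <- mentioned
  if (anyDuplicated(species)) stop("duplicate species ids")
  if (length(species) == 0) stop("at least one species is required")
  missing_sp <- setdiff(mentioned, species)
  if (length(missing_sp) > 0)
    stop("edge references missing species: ", paste(missing_sp, collapse = ", "))

  used_syms <- unlist(lapply(reactions, function(r)
    c(as.character(r$inputs), as.character(r$outputs))))
  fresh_i <- 0
  fresh_r <- function() {
    repeat {
      fresh_i <<- fresh_i + 1
      cand <- paste0("r", fresh_i)
      if (!any(grepl(cand, used_syms, fixed = TRUE))) return(cand)
    }
  }

  jac <- list(); stoich <- list()
  for (rid in names(reactions)) {
    r <- reactions[[rid]]
    ins <- r$inputs %||% character(0)
    outs <- r$outputs
    if (length(outs) == 0) stop("reaction '", rid, "' has no stoichiometric outputs")
    if (anyDuplicated(names(ins))) stop("duplicate Jacobian edge in reaction ", rid)
    if (anyDuplicated(names(outs))) stop("duplicate stoichiometric edge in reaction ", rid)
    for (sp in names(ins)) {
      w <- parse_weight(ins[[sp]], default_sym = NULL, default_unit = FALSE)
      if (is.na(w$w_sym) && is.na(w$w_num)) w$w_sym <- fresh_r()
      jac[[length(jac) + 1]] <- tibble::tibble(
        species = sp, reaction = rid, sign = w$sign,
        w_num = w$w_num, w_den = w$w_den, w_sym = w$w_sym)
    }
    for (sp in names(outs)) {
      w <- parse_weight(outs[[sp]], default_unit = TRUE)
      stoich[[length(stoich) + 1]] <- tibble::tibble(
        reaction = rid, species = sp, sign = w$sign,
        w_num = w$w_num, w_den = w$w_den, w_sym = w$w_sym)
    }
  }
  jac <- if (length(jac)) dplyr::bind_rows(jac) else
    tibble::tibble(species = character(), reaction = character(),
                   sign = integer(), w_num = numeric(), w_den = numeric(),
                   w_sym = character())
  stoich <- dplyr::bind_rows(stoich)

  is_orphan <- !(names(reactions) %in% jac$reaction)
  childless <- !(species %in% jac$species)

  bad <- setdiff(clamped, species)
  if (length(bad)) stop("clamped species not in species list: ",
                        paste(bad, collapse = ", "))

  topo <- structure(list(
    species = tibble::tibble(id = species, clamped = species %in% clamped,
                             childless = childless),
    reactions = tibble::tibble(id = names(reactions), is_orphan = is_orphan),
    jac = jac,
    stoich = stoich
  ), class = "influence_topology")
  validate_topology(topo)
  topo
}

validate_topology <- function(topo) {
  stopifnot(inherits(topo, "influence_topology"))
  if (anyDuplicated(topo$species$id)) stop("duplicate species ids")
  if (anyDuplicated(topo$reactions$id)) stop("duplicate reaction ids")
  if (nrow(topo$jac)) {
    if (any(!topo$jac$species %in% topo$species$id) ||
        any(!topo$jac$reaction %in% topo$reactions$id))
      stop("Jacobian edge references a missing node")
    if (anyDuplicated(paste(topo$jac$species, topo$jac$reaction)))
      stop("duplicate Jacobian edge")
  }
  if (any(!topo$stoich$species %in% topo$species$id) ||
      any(!topo$stoich$reaction %in% topo$reactions$id))
    stop("stoichiometric edge references a missing node")
  if (anyDuplicated(paste(topo$stoich$reaction, topo$stoich$species)))
    stop("duplicate stoichiometric edge")
  orphans <- topo$reactions$id[topo$reactions$is_orphan]
  if (any(topo$jac$reaction %in% orphans))
    stop("orphan reaction cannot receive Jacobian edges")
  no_out <- setdiff(topo$reactions$id, topo$stoich$reaction)
  if (length(no_out)) stop("reaction with no outputs: ",
                           paste(no_out, collapse = ", "))
  w_ok <- function(e) all(is.na(e$w_num) | (e$w_num > 0 & e$w_den > 0))
  if (!w_ok(topo$jac) || !w_ok(topo$stoich))
    stop("numeric edge magnitudes must be strictly positive")
  invisible(topo)
}

# species count n, reaction count m (orphans excluded), edge counts S and J
topo_counts <- function(topo) {
  keep <- !topo$reactions$is_orphan
  non_orphan <- topo$reactions$id[keep]
  list(n = nrow(topo$species),
       m = sum(keep),
       n_orphan_reactions = sum(!keep),
       S = sum(topo$stoich$reaction %in% non_orphan),
       J = nrow(topo$jac))
}

#' @export
print.influence_topology <- function(x, ...) {
  ct <- topo_counts(x)
  cat("<influence_topology> ", ct$n, " species, ", ct$m, " reactions",
      if (ct$n_orphan_reactions) paste0(" (+", ct$n_orphan_reactions, " orphan)"),
      ", S = ", ct$S, " stoichiometric / J = ", ct$J, " Jacobian edges\n",
      sep = "")
  u <- sum(is.na(x$jac$sign)) + sum(is.na(x$stoich$sign))
  if (u > 0) cat("  ", u, " edge(s) with unknown sign\n", sep = "")
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' One-row topology summary
#' @param x an `influence_topology`.
#' @param ... unused.
#' @return Tibble with node and edge counts and the number of unknown signs.
#' @method glance influence_topology
#' @export
glance.influence_topology <- function(x, ...) {
  ct <- topo_counts(x)
  tibble::tibble(n_species = ct$n, n_reactions = ct$m,
                 n_orphan_reactions = ct$n_orphan_reactions,
                 S = ct$S, J = ct$J,
                 n_unknown_signs = sum(is.na(x$jac$sign)) +
                   sum(is.na(x$stoich$sign)),
                 n_clamped = sum(x$species$clamped),
                 n_childless = sum(x$species$childless))
}

edge_weight_poly <- function(row) {
  if (!is.na(row$w_sym)) poly_sym(row$w_sym) else poly_const(row$w_num, row$w_den)
}

# canonical edge id strings, Jacobian edges first
edge_ids <- function(topo) {
  c(paste0("J:", topo$jac$species, ":", topo$jac$reaction),
    paste0("S:", topo$stoich$reaction, ":", topo$stoich$species))
}

#' Enumerate fixed-sign topologies from unknown-sign edges
#'
#' Every edge with sign `?` is a superposed activation/inhibition; this
#' expands the `2^u` concrete sign assignments, in deterministic order:
#' unknown edges sorted by canonical edge id, `+` enumerated before `-`.
#'
#' @param topo an `influence_topology`.
#' @return List of fixed-sign `influence_topology` objects (the input alone
#'   if it has no unknown signs).
#' @export
expand_sign_assignments <- function(topo) {
  validate_topology(topo)
  jac_na <- which(is.na(topo$jac$sign))
  st_na <- which(is.na(topo$stoich$sign))
  ids <- c(
    if (length(jac_na)) paste0("J:", topo$jac$species[jac_na], ":",
                               topo$jac$reaction[jac_na]),
    if (length(st_na)) paste0("S:", topo$stoich$reaction[st_na], ":",
                              topo$stoich$species[st_na]))
  if (is.null(ids)) ids <- character(0)
  slots <- tibble::tibble(
    id = ids,
    table = c(rep("jac", length(jac_na)), rep("stoich", length(st_na))),
    row = c(jac_na, st_na)
  )
  slots <- slots[order(slots$id), ]
  u <- nrow(slots)
  if (u == 0) return(list(topo))
  if (u > 16) stop("refusing to expand more than 2^16 sign assignments")
  out <- vector("list", 2^u)
  for (g in 0:(2^u - 1)) {
    t2 <- topo
    for (s in seq_len(u)) {
      # first edge on the highest bit (varies slowest); bit 0 is '+'
      bit <- bitwAnd(g, bitwShiftL(1L, u - s)) != 0
      t2[[slots$table[s]]]$sign[slots$row[s]] <- if (bit) -1L else 1L
    }
    out[[g + 1]] <- t2
  }
  out
}

#' Assemble the transition (community) matrix H
#'
#' `H[i, j] = sum_k jac(i -> k) * stoich(k -> j)`: rows are indexed by the
#' differentiating (input) species, columns by the affected species, i.e. the
#' perturbation acts as a row vector on the left. Spectra are
#' transpose-invariant, so stability conclusions do not depend on this
#' convention, but it is fixed here to avoid silent transposition bugs.
#'
#' @param topo fixed-sign `influence_topology`.
#' @param values named numeric vector giving a value for every symbolic edge
#'   magnitude; may be `NULL` when all magnitudes are numeric.
#' @return Numeric `n x n` matrix with species ids as dimnames.
#' @export
assemble_transition_matrix <- function(topo, values = NULL) {
  validate_topology(topo)
  if (any(is.na(topo$jac$sign)) || any(is.na(topo$stoich$sign)))
    stop("unknown-sign edges: expand_sign_assignments() first")
  sp <- topo$species$id[!topo$species$clamped]
  rx <- topo$reactions$id
  Rm <- matrix(0, nrow = length(sp), ncol = length(rx),
               dimnames = list(sp, rx))
  Sm <- matrix(0, nrow = length(rx), ncol = length(sp),
               dimnames = list(rx, sp))
  wt <- function(row) {
    if (!is.na(row$w_sym)) {
      v <- values[row$w_sym]
      if (is.null(values) || is.na(v)) stop("missing weight for symbol: ", row$w_sym)
      if (v < 0) stop("symbolic magnitudes must be assigned non-negative values")
      unname(v)
    } else row$w_num / row$w_den
  }
  for (i in seq_len(nrow(topo$jac))) {
    e <- topo$jac[i, ]
    if (!e$species %in% sp) next
    Rm[e$species, e$reaction] <- e$sign * wt(e)
  }
  for (i in seq_len(nrow(topo$stoich))) {
    e <- topo$stoich[i, ]
    if (!e$species %in% sp) next
    Sm[e$reaction, e$species] <- e$sign * wt(e)
  }
  Rm %*% Sm
}

# exact/symbolic H as a cpoly list-matrix (same row convention)
transition_matrix_poly <- function(topo, values = NULL) {
  if (any(is.na(topo$jac$sign)) || any(is.na(topo$stoich$sign)))
    stop("unknown-sign edges: expand_sign_assignments() first")
  sp <- topo$species$id[!topo$species$clamped]
  n <- length(sp)
  H <- matrix(rep(list(p_zero()), n * n), nrow = n, ncol = n,
              dimnames = list(sp, sp))
  wt <- function(row) {
    p <- if (!is.na(row$w_sym)) {
      if (!is.null(values) && row$w_sym %in% names(values))
        as_cpoly(values[[row$w_sym]]) else poly_sym(row$w_sym)
    } else poly_const(row$w_num, row$w_den)
    p_scale(p, row$sign)
  }
  for (k in seq_len(nrow(topo$jac))) {
    je <- topo$jac[k, ]
    if (!je$species %in% sp) next
    outs <- topo$stoich[topo$stoich$reaction == je$reaction, ]
    for (l in seq_len(nrow(outs))) {
      se <- outs[l, ]
      if (!se$species %in% sp) next
      i <- match(je$species, sp); j <- match(se$species, sp)
      H[[i, j]] <- p_add(H[[i, j]], p_mul(wt(je), wt(se)))
    }
  }
  H
}
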