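# Bipartite cycle enumeration and the cycle expansion of principal minors.
#
# Every principal minor b_q of the transition matrix equals the signed sum
# over all combinations of pairwise non-overlapping bipartite cycles of total
# species-length q (a bipartite sharpening of Sachs' theorem): combinations
# may share neither a species nor a reaction, and each combination carries
# the coefficient (-1)^(number of even-length cycles in it).

#' Enumerate the simple bipartite cycles of an influence topology
#'
#' Alternating species/reaction directed cycles, each species and each
#' reaction used at most once. Enumeration anchors each cycle at its minimal
#' node (depth-first search restricted to nodes not below the anchor), so
#' every cycle is reported exactly once; orphan reactions cannot lie on a
#' cycle and are ignored.
#'
#' @param topo fixed-sign `influence_topology`.
#' @param max_cycles guard rail; enumeration stops with an error beyond this.
#' @return Tibble, one row per cycle ordered by species-length then canonical
#'   key: `id`, `length` (number of species), `sign`, list-columns `species`,
#'   `reactions` (in cycle order, starting at the lexicographically smallest
#'   species), `weight` (signed `cpoly` product of the edge values) and
#'   `edge_keys` (canonical edge ids, for overlap barcodes).
#' @export
enumerate_cycles <- function(topo, max_cycles = 10000) {
  validate_topology(topo)
  if (any(is.na(topo$jac$sign)) || any(is.na(topo$stoich$sign)))
    stop("unknown-sign edges: expand_sign_assignments() first")
  sp <- topo$species$id[!topo$species$clamped]   # clamped species are fixed
  rx <- topo$reactions$id[!topo$reactions$is_orphan]
  nodes <- c(paste0("x|", sort(sp)), paste0("v|", sort(rx)))
  nidx <- stats::setNames(seq_along(nodes), nodes)

  adj <- vector("list", length(nodes))
  names(adj) <- nodes
  for (i in seq_len(nrow(topo$jac))) {
    e <- topo$jac[i, ]
    if (!e$species %in% sp) next
    from <- paste0("x|", e$species); to <- paste0("v|", e$reaction)
    adj[[from]] <- c(adj[[from]], to)
  }
  for (i in seq_len(nrow(topo$stoich))) {
    e <- topo$stoich[i, ]
    if (!e$reaction %in% rx || !e$species %in% sp) next
    from <- paste0("v|", e$reaction); to <- paste0("x|", e$species)
    adj[[from]] <- c(adj[[from]], to)
  }
  adj <- lapply(adj, function(a) if (is.null(a)) character(0) else sort(a))

  cycles <- list()
  path <- character(0)
  dfs <- function(anchor, node) {
    for (nb in adj[[node]]) {
      if (nidx[nb] < nidx[anchor]) next
      if (nb == anchor) {
        cycles[[length(cycles) + 1]] <<- c(path, node)
        if (length(cycles) > max_cycles)
          stop("more than ", max_cycles, " bipartite cycles; refusing")
      } else if (!nb %in% path && nb != node) {
        path <<- c(path, node)
        dfs(anchor, nb)
        path <<- path[-length(path)]
      }
    }
  }
  for (a in nodes) {
    path <- character(0)
    dfs(a, a)
  }

  if (length(cycles) == 0) {
    return(tibble::tibble(id = character(), length = integer(),
                          sign = integer(), species = list(),
                          reactions = list(), weight = list(),
                          edge_keys = list()))
  }

  jkey <- function(s, r) paste0("J:", s, ":", r)
  skey <- function(r, s) paste0("S:", r, ":", s)
  jrow <- stats::setNames(seq_len(nrow(topo$jac)),
                          jkey(topo$jac$species, topo$jac$reaction))
  srow <- stats::setNames(seq_len(nrow(topo$stoich)),
                          skey(topo$stoich$reaction, topo$stoich$species))

  rec <- lapply(cycles, function(cyc) {
    kinds <- substr(cyc, 1, 1)
    ids <- substring(cyc, 3)
    # rotate so the cycle starts at the lexicographically smallest species
    sp_pos <- which(kinds == "x")
    start <- sp_pos[order(ids[sp_pos])[1]]
    ord <- c(seq(start, length(cyc)), seq_len(start - 1))
    kinds <- kinds[ord]; ids <- ids[ord]
    species <- ids[kinds == "x"]; reactions <- ids[kinds == "v"]
    sgn <- 1L
    w <- p_one()
    L <- length(species)
    for (i in seq_len(L)) {
      s <- species[i]; r <- reactions[i]; s2 <- species[if (i == L) 1 else i + 1]
      je <- topo$jac[jrow[[jkey(s, r)]], ]
      se <- topo$stoich[srow[[skey(r, s2)]], ]
      sgn <- sgn * je$sign * se$sign
      w <- p_mul(w, p_mul(edge_weight_poly(je), edge_weight_poly(se)))
    }
    list(species = species, reactions = reactions, length = L,
         sign = as.integer(sgn), weight = p_scale(w, sgn),
         edge_keys = unlist(lapply(seq_len(L), function(i) {
           s2 <- species[if (i == L) 1 else i + 1]
           c(jkey(species[i], reactions[i]), skey(reactions[i], s2))
         })),
         key = paste(rbind(species, reactions), collapse = ">"))
  })

  keys <- vapply(rec, `[[`, character(1), "key")
  lens <- vapply(rec, `[[`, integer(1), "length")
  o <- order(lens, keys)
  rec <- rec[o]
  tibble::tibble(
    id = paste0("C", seq_along(rec)),
    length = vapply(rec, `[[`, integer(1), "length"),
    sign = vapply(rec, `[[`, integer(1), "sign"),
    species = lapply(rec, `[[`, "species"),
    reactions = lapply(rec, `[[`, "reactions"),
    weight = lapply(rec, `[[`, "weight"),
    edge_keys = lapply(rec, `[[`, "edge_keys")
  )
}

#' Non-overlapping cycle combinations of total length q
#'
#' All subsets of pairwise species- and reaction-disjoint cycles whose
#' species-lengths sum to `q`, each with coefficient `(-1)^(number of
#' even-length member cycles)`. `q = 0` yields the single empty combination
#' with coefficient +1 (`b_0 = 1`).
#'
#' @param cycles tibble from [enumerate_cycles()].
#' @param q combination order (non-negative integer).
#' @return Tibble: `cycles` (list of cycle ids), `coefficient`, `monomial`
#'   (list of `cpoly` products of the member weights, including the
#'   coefficient).
#' @export
nonoverlapping_combinations <- function(cycles, q) {
  stopifnot(q >= 0, q == round(q))
  out <- list()
  nc <- nrow(cycles)
  recurse <- function(i, rem, used_sp, used_rx, chosen) {
    if (rem == 0) {
      out[[length(out) + 1]] <<- chosen
      return()
    }
    if (i > nc) return()
    for (j in i:nc) {
      if (cycles$length[j] > rem) next
      if (any(cycles$species[[j]] %in% used_sp)) next
      if (any(cycles$reactions[[j]] %in% used_rx)) next
      recurse(j + 1, rem - cycles$length[j],
              c(used_sp, cycles$species[[j]]),
              c(used_rx, cycles$reactions[[j]]),
              c(chosen, j))
    }
  }
  recurse(1, q, character(0), character(0), integer(0))
  if (length(out) == 0) {
    return(tibble::tibble(cycles = list(), coefficient = integer(),
                          monomial = list()))
  }
  ids <- lapply(out, function(ix) cycles$id[ix])
  coefs <- vapply(out, function(ix)
    as.integer((-1)^sum(cycles$length[ix] %% 2 == 0)), integer(1))
  monos <- lapply(seq_along(out), function(i)
    p_scale(p_prod(cycles$weight[out[[i]]]), coefs[i]))
  tibble::tibble(cycles = ids, coefficient = coefs, monomial = monos)
}

#' Principal minors from bipartite cycles
#'
#' Computes `b_0 .. b_n` of the transition matrix as signed sums of
#' non-overlapping bipartite cycle products, exactly (rational/symbolic).
#'
#' @param topo fixed-sign `influence_topology`, or a cycle tibble from
#'   [enumerate_cycles()] (then pass `n`).
#' @param n number of species; inferred when `topo` is a topology.
#' @return A `minor_set`: list with `b` (list of `cpoly`, `b[[q+1]]` is
#'   `b_q`), `combos` (per-q combination tables) and `n`.
#' @export
principal_minors <- function(topo, n = NULL) {
  if (inherits(topo, "influence_topology")) {
    n <- sum(!topo$species$clamped)
    cycles <- enumerate_cycles(topo)
  } else {
    cycles <- topo
    if (is.null(n)) stop("supply n when passing a cycle table")
  }
  b <- vector("list", n + 1)
  combos <- vector("list", n + 1)
  for (q in 0:n) {
    cb <- nonoverlapping_combinations(cycles, q)
    combos[[q + 1]] <- cb
    b[[q + 1]] <- if (nrow(cb) == 0) p_zero() else p_sum(cb$monomial)
  }
  structure(list(b = b, combos = combos, n = n, cycles = cycles),
            class = "minor_set")
}

#' @export
print.minor_set <- function(x, ...) {
  cat("<minor_set> n =", x$n, "\n")
  for (q in 0:x$n)
    cat("  b_", q, " = ", format(x$b[[q + 1]]), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy a minor set
#' @param x a `minor_set`.
#' @param ... unused.
#' @return Tibble with one row per order `q`: the expression, the number of
#'   contributing cycle combinations.
#' @method tidy minor_set
#' @export
tidy.minor_set <- function(x, ...) {
  tibble::tibble(
    q = 0:x$n,
    expression = vapply(x$b, format, character(1)),
    n_combinations = vapply(x$combos, nrow, integer(1))
  )
}

#' Per-order combination report
#'
#' The cycle-combination table behind each principal minor: which cycles,
#' the (-1)^(even cycles) coefficient, and the resulting monomial.
#'
#' @param minors a `minor_set`.
#' @param path optional CSV output path.
#' @return Tibble with columns `q`, `cycles`, `coefficient`, `monomial`.
#' @export
combination_table <- function(minors, path = NULL) {
  rows <- purrr::map_dfr(0:minors$n, function(q) {
    cb <- minors$combos[[q + 1]]
    if (nrow(cb) == 0) return(tibble::tibble())
    tibble::tibble(
      q = q,
      cycles = vapply(cb$cycles, function(z)
        if (length(z)) paste(z, collapse = "+") else "(empty)", character(1)),
      coefficient = cb$coefficient,
      monomial = vapply(cb$monomial, format, character(1))
    )
  })
  if (!is.null(path)) utils::write.csv(rows, path, row.names = FALSE)
  rows
}
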