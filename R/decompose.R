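# General-network analysis: special-node classification, upstream/downstream
# level decomposition via strongly connected components, and node-negation
# canonicalization of edge signs.

#' Classify orphan and childless nodes
#'
#' Orphan species have no reaction parent (clamped species are forced into
#' this class); childless species feed no reaction (pure bookkeeping);
#' orphan reactions depend on no species (constant inputs, kept as dashed
#' nodes but outside all cycle algebra); childless reactions output to no
#' species in the network under consideration.
#'
#' @param topo an `influence_topology`.
#' @return A `node_classification`: four id vectors.
#' @export
classify_special_nodes <- function(topo) {
  validate_topology(topo)
  sp <- topo$species$id
  rx <- topo$reactions$id
  orphan_species <- sp[!(sp %in% topo$stoich$species) | topo$species$clamped]
  childless_species <- sp[!(sp %in% topo$jac$species)]
  orphan_reactions <- rx[!(rx %in% topo$jac$reaction)]
  childless_reactions <- rx[!(rx %in% topo$stoich$reaction)]
  structure(list(orphan_species = orphan_species,
                 childless_species = childless_species,
                 orphan_reactions = orphan_reactions,
                 childless_reactions = childless_reactions),
            class = "node_classification")
}

#' @export
print.node_classification <- function(x, ...) {
  cat("<node_classification>\n")
  for (f in names(x)) {
    cat("  ", f, ": ",
        if (length(x[[f]])) paste(x[[f]], collapse = ", ") else "(none)",
        "\n", sep = "")
  }
  invisible(x)
}

topo_igraph <- function(topo) {
  sp <- paste0("x|", topo$species$id)
  rx <- paste0("v|", topo$reactions$id)
  edges <- character(0)
  for (i in seq_len(nrow(topo$jac)))
    edges <- c(edges, paste0("x|", topo$jac$species[i]),
               paste0("v|", topo$jac$reaction[i]))
  for (i in seq_len(nrow(topo$stoich)))
    edges <- c(edges, paste0("v|", topo$stoich$reaction[i]),
               paste0("x|", topo$stoich$species[i]))
  igraph::graph_from_data_frame(
    d = if (length(edges)) data.frame(
      from = edges[seq(1, length(edges), 2)],
      to = edges[seq(2, length(edges), 2)]) else
        data.frame(from = character(), to = character()),
    directed = TRUE, vertices = data.frame(name = c(sp, rx)))
}

# induced sub-topology on a set of bare node names (species/reaction ids)
induced_topology <- function(topo, species_ids, reaction_ids) {
  jac <- topo$jac[topo$jac$species %in% species_ids &
                    topo$jac$reaction %in% reaction_ids, ]
  stoich <- topo$stoich[topo$stoich$species %in% species_ids &
                          topo$stoich$reaction %in% reaction_ids, ]
  keep_rx <- intersect(topo$reactions$id, reaction_ids)
  keep_rx <- keep_rx[keep_rx %in% stoich$reaction]   # every reaction needs outputs
  jac <- jac[jac$reaction %in% keep_rx, ]
  stoich <- stoich[stoich$reaction %in% keep_rx, ]
  structure(list(
    species = topo$species[topo$species$id %in% species_ids, ],
    reactions = tibble::tibble(id = keep_rx,
                               is_orphan = !(keep_rx %in% jac$reaction)),
    jac = jac, stoich = stoich), class = "influence_topology")
}

# sign of a symbolic expression whose parameters are positive symbols:
# +1/-1 when all coefficients agree, 0 for the zero polynomial, NA otherwise
definite_sign <- function(p) {
  if (p_is_zero(p)) return(0L)
  if (all(p$coefn > 0)) return(1L)
  if (all(p$coefn < 0)) return(-1L)
  NA_integer_
}

#' Upstream/downstream level decomposition
#'
#' Partitions the bipartite digraph into its strongly connected components;
#' the components containing at least one cycle are the network's "levels",
#' ordered upstream first along the condensation DAG. Each level induces its
#' own influence topology; an autonomous level (no unstable or oscillatory
#' level upstream) gets a first-order stability verdict where the reduced
#' determinant signs are parameter-independent. Levels fed by a
#' non-converging upstream level are flagged non-autonomous: first-order
#' analysis about a steady state does not apply to them.
#'
#' @param topo fixed-sign `influence_topology`.
#' @return A `level_decomposition`: `levels` tibble (`level`, `depth`,
#'   `species`, `reactions`, `topology`, `verdict`), `dag_edges`,
#'   `acyclic_remainder`.
#' @export
level_decomposition <- function(topo) {
  validate_topology(topo)
  if (any(is.na(topo$jac$sign)) || any(is.na(topo$stoich$sign)))
    stop("unknown-sign edges: expand_sign_assignments() first")
  g <- topo_igraph(topo)
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  # a bipartite SCC contains a cycle iff it has more than one node
  cyc_comp <- which(tabulate(memb, comp$no) > 1)

  cg <- igraph::contract(g, memb)
  cg <- igraph::simplify(cg)
  topo_order <- as.integer(igraph::topo_sort(cg, mode = "out"))
  depth <- rep(0L, comp$no)
  for (c0 in topo_order) {
    preds <- as.integer(igraph::neighbors(cg, c0, mode = "in"))
    if (length(preds)) depth[c0] <- max(depth[preds]) + 1L
  }

  ord <- cyc_comp[order(depth[cyc_comp], cyc_comp)]
  comp_verdict <- rep(NA_character_, comp$no)
  rows <- list()
  lev <- 0
  verdict_of <- function(sub) {
    red <- tryCatch(reduce_topology(sub), error = function(e) NULL)
    if (is.null(red)) return("indeterminate")
    signs <- vapply(red$hurwitz$deltas, definite_sign, integer(1))
    if (all(!is.na(signs)) && all(signs == 0))
      return("indeterminate (all Hurwitz determinants zero)")
    if (all(!is.na(signs)) && all(signs > 0)) return("stable")
    if (any(!is.na(signs) & signs < 0)) return("unstable")
    "parameter-dependent"
  }
  for (c0 in ord) {
    lev <- lev + 1
    nodes <- names(memb)[memb == c0]
    sp <- substring(nodes[startsWith(nodes, "x|")], 3)
    rx <- substring(nodes[startsWith(nodes, "v|")], 3)
    sub <- induced_topology(topo, sp, rx)
    anc <- setdiff(as.integer(igraph::subcomponent(cg, c0, mode = "in")), c0)
    anc <- intersect(anc, cyc_comp)
    upstream_bad <- any(!is.na(comp_verdict[anc]) &
                          comp_verdict[anc] != "stable")
    verdict <- if (upstream_bad) "non-autonomous (driven by upstream level)"
               else verdict_of(sub)
    comp_verdict[c0] <- verdict
    rows[[lev]] <- tibble::tibble(
      level = lev, depth = depth[c0],
      species = list(sort(sp)), reactions = list(sort(rx)),
      topology = list(sub), verdict = verdict)
  }
  levels <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(level = integer(), depth = integer(), species = list(),
                   reactions = list(), topology = list(), verdict = character())

  acyclic <- names(memb)[memb %in% setdiff(seq_len(comp$no), cyc_comp)]
  el <- igraph::as_edgelist(g)
  cross <- el[memb[el[, 1]] != memb[el[, 2]], , drop = FALSE]
  structure(list(levels = levels,
                 dag_edges = tibble::tibble(from = cross[, 1], to = cross[, 2]),
                 acyclic_remainder = sort(acyclic)),
            class = "level_decomposition")
}

#' @export
print.level_decomposition <- function(x, ...) {
  cat("<level_decomposition> ", nrow(x$levels), " cycle-containing level(s)\n",
      sep = "")
  for (i in seq_len(nrow(x$levels))) {
    l <- x$levels[i, ]
    cat("  level ", l$level, " (depth ", l$depth, "): {",
        paste(l$species[[1]], collapse = ", "), "} via {",
        paste(l$reactions[[1]], collapse = ", "), "} - ", l$verdict, "\n",
        sep = "")
  }
  if (length(x$acyclic_remainder))
    cat("  acyclic remainder: ",
        paste(x$acyclic_remainder, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# edge-sign bit string in canonical edge order (Jacobian edges first,
# each sorted lexicographically); '-' maps to 1 so "all arrows" is minimal
sign_string <- function(topo) {
  jo <- order(topo$jac$species, topo$jac$reaction)
  so <- order(topo$stoich$reaction, topo$stoich$species)
  paste(c(ifelse(topo$jac$sign[jo] > 0, "0", "1"),
          ifelse(topo$stoich$sign[so] > 0, "0", "1")), collapse = "")
}

negate_node <- function(topo, node, kind) {
  if (kind == "species") {
    i <- topo$jac$species == node
    topo$jac$sign[i] <- -topo$jac$sign[i]
    i <- topo$stoich$species == node
    topo$stoich$sign[i] <- -topo$stoich$sign[i]
  } else {
    i <- topo$jac$reaction == node
    topo$jac$sign[i] <- -topo$jac$sign[i]
    i <- topo$stoich$reaction == node
    topo$stoich$sign[i] <- -topo$stoich$sign[i]
  }
  topo
}

#' Canonical sign form under node negation
#'
#' Negating a species (`y = -x`) or a reaction (`w = -v`) flips all its
#' incident edge signs while leaving every cycle sign, hence all principal
#' minors and Hurwitz determinants, unchanged. This picks the canonical
#' representative of that degeneracy orbit: the negation subset minimising
#' the edge-sign bit string (canonical edge order; ties broken by fewest and
#' then lexicographically smallest negated nodes). The search is exhaustive
#' over all `2^(n+m)` subsets up to `n + m <= exhaustive_limit` nodes and
#' greedy-to-fixpoint beyond (the greedy result may then be a local optimum
#' of the orbit).
#'
#' @param topo fixed-sign `influence_topology`.
#' @param exhaustive_limit switch-over size for the exhaustive search.
#' @return A `canonical_form`: `topology` (canonical signs),
#'   `negated_nodes` (character vector), `sign_string`.
#' @export
canonical_sign_form <- function(topo, exhaustive_limit = 14) {
  validate_topology(topo)
  if (any(is.na(topo$jac$sign)) || any(is.na(topo$stoich$sign)))
    stop("unknown-sign edges: expand_sign_assignments() first")
  nodes <- c(paste0("species:", sort(topo$species$id)),
             paste0("reaction:", sort(topo$reactions$id)))
  nn <- length(nodes)
  node_sp <- sub("^species:", "", nodes[startsWith(nodes, "species:")])
  node_rx <- sub("^reaction:", "", nodes[startsWith(nodes, "reaction:")])
  # incidence: rows = edges in canonical order, cols = nodes
  jo <- order(topo$jac$species, topo$jac$reaction)
  so <- order(topo$stoich$reaction, topo$stoich$species)
  base_bits <- c(topo$jac$sign[jo] < 0, topo$stoich$sign[so] < 0)
  inc <- cbind(
    rbind(outer(topo$jac$species[jo], node_sp, "=="),
          outer(topo$stoich$species[so], node_sp, "==")),
    rbind(outer(topo$jac$reaction[jo], node_rx, "=="),
          outer(topo$stoich$reaction[so], node_rx, "==")))
  string_for <- function(sel) {
    flips <- (inc %*% sel) %% 2
    paste(as.integer(xor(base_bits, flips == 1)), collapse = "")
  }
  apply_set <- function(set) {
    t2 <- topo
    for (nd in nodes[set]) {
      parts <- strsplit(nd, ":", fixed = TRUE)[[1]]
      t2 <- negate_node(t2, parts[2], parts[1])
    }
    t2
  }
  if (nn <= exhaustive_limit) {
    best <- NULL; best_key <- NULL
    for (mask in 0:(2^nn - 1)) {
      sel <- as.integer(bitwAnd(mask, bitwShiftL(1L, seq_len(nn) - 1)) != 0)
      key <- list(string_for(sel), sum(sel),
                  paste(nodes[sel == 1], collapse = ","))
      better <- is.null(best_key) ||
        key[[1]] < best_key[[1]] ||
        (key[[1]] == best_key[[1]] && (key[[2]] < best_key[[2]] ||
          (key[[2]] == best_key[[2]] && key[[3]] < best_key[[3]])))
      if (better) { best_key <- key; best <- which(sel == 1) }
    }
    chosen <- best
  } else {
    chosen <- integer(0)
    repeat {
      sel <- as.integer(seq_len(nn) %in% chosen)
      cur <- string_for(sel)
      improved <- FALSE
      for (i in seq_len(nn)) {
        cand <- if (i %in% chosen) setdiff(chosen, i) else c(chosen, i)
        if (string_for(as.integer(seq_len(nn) %in% cand)) < cur) {
          chosen <- cand
          improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
  }
  t2 <- apply_set(chosen)
  structure(list(topology = t2,
                 negated_nodes = nodes[sort(chosen)],
                 sign_string = sign_string(t2)),
            class = "canonical_form")
}

#' @export
print.canonical_form <- function(x, ...) {
  cat("<canonical_form> sign string ", x$sign_string, "\n", sep = "")
  cat("  negated nodes: ",
      if (length(x$negated_nodes)) paste(x$negated_nodes, collapse = ", ")
      else "(none)", "\n", sep = "")
  invisible(x)
}

#' Level report
#'
#' Tidy (or JSON) report of a level decomposition: levels, members,
#' classifications, per-level verdicts.
#'
#' @param decomp a `level_decomposition`.
#' @param topo the original topology (for the node classification section).
#' @param path optional output path; `.json` extension writes JSON,
#'   anything else CSV.
#' @return A tibble.
#' @export
level_report <- function(decomp, topo = NULL, path = NULL) {
  rows <- purrr::map_dfr(seq_len(nrow(decomp$levels)), function(i) {
    l <- decomp$levels[i, ]
    tibble::tibble(level = l$level, depth = l$depth,
                   species = paste(l$species[[1]], collapse = " "),
                   reactions = paste(l$reactions[[1]], collapse = " "),
                   verdict = l$verdict)
  })
  if (!is.null(path)) {
    if (grepl("\\.json$", path)) {
      jsonlite::write_json(rows, path, dataframe = "rows", pretty = TRUE)
    } else utils::write.csv(rows, path, row.names = FALSE)
  }
  rows
}
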