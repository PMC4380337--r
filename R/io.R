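# Serialization: a small versioned JSON dialect (invented here; no on-disk
# format exists in the literature for DSR graphs) plus DOT export for
# visualization. Round trips preserve node order, signs and magnitudes.

SCHEMA_ID <- "influence-topology/1"

fmt_weight <- function(sign, w_num, w_den, w_sym) {
  s <- if (is.na(sign)) "?" else if (sign < 0) "-" else "+"
  mag <- if (!is.na(w_sym)) w_sym
         else if (w_den == 1) as.character(w_num)
         else paste0(w_num, "/", w_den)
  paste0(s, mag)
}

#' Serialize an influence topology to JSON
#'
#' Dialect: `{"schema": "influence-topology/1", "species": [{"id",
#' "clamped"}], "reactions": [{"id", "inputs": {...}, "outputs": {...}}]}`.
#' An orphan reaction has empty `inputs`. Edge values are sign-prefixed
#' magnitudes (`"+sigma1"`, `"-1"`, `"?r2"`). Output is normalised, so one
#' write/read/write pass is byte-stable.
#'
#' @param topo an `influence_topology`.
#' @param path optional file path; when `NULL` the JSON text is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
write_topology <- function(topo, path = NULL) {
  validate_topology(topo)
  rx <- lapply(seq_len(nrow(topo$reactions)), function(i) {
    rid <- topo$reactions$id[i]
    je <- topo$jac[topo$jac$reaction == rid, ]
    se <- topo$stoich[topo$stoich$reaction == rid, ]
    ins <- stats::setNames(
      lapply(seq_len(nrow(je)), function(k)
        fmt_weight(je$sign[k], je$w_num[k], je$w_den[k], je$w_sym[k])),
      je$species)
    outs <- stats::setNames(
      lapply(seq_len(nrow(se)), function(k)
        fmt_weight(se$sign[k], se$w_num[k], se$w_den[k], se$w_sym[k])),
      se$species)
    list(id = rid, inputs = ins, outputs = outs)
  })
  doc <- list(
    schema = SCHEMA_ID,
    species = lapply(seq_len(nrow(topo$species)), function(i)
      list(id = topo$species$id[i], clamped = topo$species$clamped[i])),
    reactions = rx
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(path)
}

#' Read an influence topology from JSON
#'
#' @param x a file path or a JSON string in the dialect written by
#'   [write_topology()].
#' @return An `influence_topology`.
#' @export
read_topology <- function(x) {
  txt <- if (length(x) == 1 && !grepl("[{]", x) && file.exists(x))
    paste(readLines(x, warn = FALSE), collapse = "\n") else x
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) stop("malformed topology document: ",
                                           conditionMessage(e)))
  if (is.null(doc$schema) || !identical(doc$schema, SCHEMA_ID))
    stop("unknown schema version: ", doc$schema %||% "<missing>")
  for (key in c("species", "reactions"))
    if (is.null(doc[[key]])) stop("document missing '", key, "' key")
  species <- vapply(doc$species, function(s) s$id, character(1))
  clamped <- species[vapply(doc$species, function(s)
    isTRUE(s$clamped), logical(1))]
  reactions <- stats::setNames(lapply(doc$reactions, function(r) {
    list(inputs = unlist(r$inputs) %||% character(0),
         outputs = unlist(r$outputs))
  }), vapply(doc$reactions, function(r) r$id, character(1)))
  build_topology(reactions, species = species, clamped = clamped)
}

#' DOT export of an influence topology
#'
#' Species are ellipses, reactions boxes (orphans dashed); positive edges get
#' normal arrowheads, negative edges "tee" (blunt) arrowheads, unknown signs
#' a diamond.
#'
#' @param topo an `influence_topology`.
#' @param path optional output file.
#' @return DOT text (invisibly if written to `path`).
#' @export
topology_to_dot <- function(topo, path = NULL) {
  validate_topology(topo)
  q <- function(x) paste0('"', x, '"')
  lines <- c("digraph influence_topology {", "  rankdir=LR;")
  for (i in seq_len(nrow(topo$species))) {
    lines <- c(lines, paste0("  ", q(topo$species$id[i]),
                             " [shape=ellipse];"))
  }
  for (i in seq_len(nrow(topo$reactions))) {
    style <- if (topo$reactions$is_orphan[i]) ", style=dashed" else ""
    lines <- c(lines, paste0("  ", q(topo$reactions$id[i]),
                             " [shape=box", style, "];"))
  }
  head_of <- function(sgn) {
    if (is.na(sgn)) "diamond" else if (sgn > 0) "normal" else "tee"
  }
  for (i in seq_len(nrow(topo$jac))) {
    e <- topo$jac[i, ]
    lbl <- fmt_weight(e$sign, e$w_num, e$w_den, e$w_sym)
    lines <- c(lines, paste0("  ", q(e$species), " -> ", q(e$reaction),
                             " [arrowhead=", head_of(e$sign),
                             ", label=", q(lbl), "];"))
  }
  for (i in seq_len(nrow(topo$stoich))) {
    e <- topo$stoich[i, ]
    lbl <- fmt_weight(e$sign, e$w_num, e$w_den, e$w_sym)
    style <- if (topo$reactions$is_orphan[match(e$reaction, topo$reactions$id)])
      ", style=dashed" else ""
    lines <- c(lines, paste0("  ", q(e$reaction), " -> ", q(e$species),
                             " [arrowhead=", head_of(e$sign), style,
                             ", label=", q(lbl), "];"))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
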