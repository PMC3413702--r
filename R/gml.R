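# Deterministic GML export/import for visual curation in Cytoscape and for
# solution visualization. The emitted dialect is standard GML (readable by
# igraph and Cytoscape); provenance travels in the Creator string because a
# timestamp-free byte-identical output is part of the contract.

gml_quote <- function(x) {
  paste0('"', gsub('"', "'", x), '"')
}

write_gml_graph <- function(g, path, states = NULL, provenance = "") {
  nodes <- tibble::tibble(
    id = seq_len(igraph::vcount(g)) - 1L,
    name = igraph::V(g)$name,
    label = igraph::V(g)$label,
    class = igraph::V(g)$class)
  el <- igraph::as_edgelist(g)
  lines <- c(
    sprintf("Creator %s", gml_quote(paste0("boolsig ",
            as.character(utils::packageVersion("boolsig")),
            if (nzchar(provenance)) paste0(" ", provenance) else ""))),
    "Version 1",
    "graph [",
    "  directed 1")
  for (i in seq_len(nrow(nodes))) {
    lines <- c(lines,
      "  node [",
      sprintf("    id %d", nodes$id[i]),
      sprintf("    name %s", gml_quote(nodes$name[i])),
      sprintf("    label %s", gml_quote(nodes$label[i])),
      sprintf("    class %s", gml_quote(nodes$class[i])),
      if (!is.null(states)) sprintf("    state %d", states[[nodes$name[i]]]),
      "  ]")
  }
  if (nrow(el)) {
    src <- nodes$id[match(el[, 1L], nodes$name)]
    tgt <- nodes$id[match(el[, 2L], nodes$name)]
    ord <- order(src, tgt)
    for (k in ord) {
      lines <- c(lines,
        "  edge [",
        sprintf("    source %d", src[k]),
        sprintf("    target %d", tgt[k]),
        "  ]")
    }
  }
  lines <- c(lines, "]")
  writeLines(lines, path)
  invisible(path)
}

#' Export a system or dependency graph as GML
#'
#' Node attributes carry the variable id (`name`), display label and node
#' class (`signal` or `reaction`). Output is deterministic: identical input
#' yields byte-identical files. Edit the file in Cytoscape (deleting nodes
#' or edges) and read it back with [import_curated_gml()].
#'
#' @param x A `boolean_system` or dependency graph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_gml <- function(x, path) {
  g <- as_dependency_graph(x)
  write_gml_graph(g, path, provenance = paste0("hash:", rlang::hash(igraph::as_edgelist(g))))
}

#' Visualize a solved network state as GML
#'
#' Hypergraph-style rendering (reaction nodes link their participants) with
#' a `state` attribute per node: 0 marks the absence of the species or the
#' inactivity of the event, 1 its presence/activity.
#'
#' @param system A `boolean_system`.
#' @param assignment Named 0/1 vector covering every variable of the system.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_solution_gml <- function(system, assignment, path) {
  stopifnot(inherits(system, "boolean_system"))
  vars <- variables(system)
  miss <- setdiff(vars, names(assignment))
  if (length(miss)) {
    rlang::abort(sprintf("assignment missing variable(s): %s",
                         paste(miss, collapse = ", ")),
                 class = "boolsig_missing_variable")
  }
  states <- as.list(stats::setNames(as.integer(assignment[vars]), vars))
  g <- dependency_graph(system)
  write_gml_graph(g, path, states = states,
                  provenance = paste0("hash:", rlang::hash(states)))
}

# Minimal parser for the GML subset this package emits (and the common
# dialect Cytoscape writes): nested key [ ... ] blocks with integer or
# quoted-string values. Returns nodes/edges with source line numbers so
# errors can point at the offending line.
parse_gml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tokens <- list()
  for (ln in seq_along(lines)) {
    text <- sub("#.*$", "", lines[ln])
    pat <- '"[^"]*"|\\[|\\]|[^][[:space:]"]+'
    for (tok in regmatches(text, gregexpr(pat, text))[[1]]) {
      tokens[[length(tokens) + 1L]] <- list(tok = tok, line = ln)
    }
  }
  pos <- 1L
  fail <- function(msg, line) {
    rlang::abort(sprintf("GML parse error at line %d: %s", line, msg),
                 class = "boolsig_gml_error")
  }
  parse_block <- function() {
    out <- list()
    while (pos <= length(tokens)) {
      tk <- tokens[[pos]]
      if (tk$tok == "]") { pos <<- pos + 1L; return(out) }
      key <- tk$tok
      if (key == "[") fail("unexpected '['", tk$line)
      pos <<- pos + 1L
      if (pos > length(tokens)) fail(sprintf("key '%s' has no value", key), tk$line)
      vt <- tokens[[pos]]
      if (vt$tok == "[") {
        pos <<- pos + 1L
        val <- parse_block()
      } else {
        pos <<- pos + 1L
        val <- if (grepl('^"', vt$tok)) gsub('^"|"$', "", vt$tok)
               else utils::type.convert(vt$tok, as.is = TRUE)
      }
      out[[length(out) + 1L]] <- list(key = key, value = val, line = tk$line)
    }
    out
  }
  top <- parse_block()
  graph <- NULL
  for (item in top) if (item$key == "graph") graph <- item
  if (is.null(graph)) rlang::abort("GML file has no graph block",
                                   class = "boolsig_gml_error")
  nodes <- list(); edges <- list()
  for (item in graph$value) {
    if (item$key == "node") {
      kv <- stats::setNames(lapply(item$value, `[[`, "value"),
                            vapply(item$value, `[[`, "", "key"))
      nodes[[length(nodes) + 1L]] <-
        list(id = kv$id,
             name = if (!is.null(kv$name)) kv$name else kv$label,
             line = item$line)
    } else if (item$key == "edge") {
      kv <- stats::setNames(lapply(item$value, `[[`, "value"),
                            vapply(item$value, `[[`, "", "key"))
      edges[[length(edges) + 1L]] <-
        list(source = kv$source, target = kv$target, line = item$line)
    }
  }
  list(nodes = nodes, edges = edges)
}

#' Read back an externally curated GML file
#'
#' Compares the GML content against the system's dependency graph: each node
#' deleted externally removes the corresponding signal or event (and all its
#' statements); each deleted edge removes the corresponding antecedent
#' membership (input, catalyst or inhibitor of an event) or derivation
#' membership (output of an event). Reading an unedited export back is the
#' identity on the statement set. Nodes in the GML that the system does not
#' know are an error with line context.
#'
#' @param system The `boolean_system` the GML was exported from.
#' @param path Path to the (possibly edited) GML file.
#' @return The curated system; actions are appended to [curation_log()].
#' @export
import_curated_gml <- function(system, path) {
  stopifnot(inherits(system, "boolean_system"))
  parsed <- parse_gml(path)
  known <- variables(system)
  id_map <- character()
  for (nd in parsed$nodes) {
    if (is.null(nd$name)) {
      rlang::abort(sprintf("GML node at line %d has no name/label", nd$line),
                   class = "boolsig_gml_error")
    }
    if (!nd$name %in% known) {
      rlang::abort(sprintf("GML line %d references unknown node '%s'",
                           nd$line, nd$name),
                   class = "boolsig_gml_error")
    }
    id_map[[as.character(nd$id)]] <- nd$name
  }
  kept_nodes <- unname(id_map)
  kept_edges <- vapply(parsed$edges, function(e) {
    s <- id_map[[as.character(e$source)]]
    t <- id_map[[as.character(e$target)]]
    if (is.null(s) || is.null(t)) {
      rlang::abort(sprintf("GML line %d references unknown node id", e$line),
                   class = "boolsig_gml_error")
    }
    paste(s, t, sep = "\r")
  }, "")

  g <- dependency_graph(system)
  el <- igraph::as_edgelist(g)
  sys_edges <- paste(el[, 1L], el[, 2L], sep = "\r")
  deleted_nodes <- setdiff(known, kept_nodes)
  deleted_edges <- setdiff(sys_edges, kept_edges)

  for (v in deleted_nodes) {
    system <- drop_variable(system, v)
    system <- curation_log_append(system, "remove-node", NA_character_, v,
                                  "node deleted in external GML curation")
  }
  remaining <- variables(system)
  for (e in deleted_edges) {
    uv <- strsplit(e, "\r", fixed = TRUE)[[1]]
    if (!all(uv %in% remaining)) next  # already gone with a deleted node
    system <- drop_edge_membership(system, uv[1L], uv[2L])
    system <- curation_log_append(system, "remove-derivation-membership",
                                  NA_character_, NA_character_,
                                  sprintf("edge %s -> %s deleted in external GML curation",
                                          uv[1L], uv[2L]))
  }
  recompile(system)
}

# Node deletion removes the variable and every statement incident to it:
# deleting an event removes the event; deleting a signal removes every
# event whose activation statement mentions it (input, catalyst or
# inhibitor) and its membership in any derivation statement.
drop_variable <- function(system, v) {
  if (v %in% system$events$id) {
    system$events <- system$events[system$events$id != v, , drop = FALSE]
  } else {
    keep <- rep(TRUE, nrow(system$events))
    for (i in seq_len(nrow(system$events))) {
      if (v %in% c(system$events$inputs[[i]], system$events$catalysts[[i]],
                   system$events$inhibitors[[i]])) {
        keep[i] <- FALSE
        next
      }
      outs <- setdiff(system$events$outputs[[i]], v)
      if (length(outs) == 0L) keep[i] <- FALSE else system$events$outputs[[i]] <- outs
    }
    system$events <- system$events[keep, , drop = FALSE]
    system$signals <- system$signals[system$signals$id != v, , drop = FALSE]
    gi <- system$general_inhibitions
    system$general_inhibitions <- gi[gi$inhibitor != v & gi$target != v, , drop = FALSE]
  }
  system
}

drop_edge_membership <- function(system, u, v) {
  if (v %in% system$events$id) {
    # signal u -> event v: antecedent literal
    i <- match(v, system$events$id)
    system$events$inputs[[i]] <- setdiff(system$events$inputs[[i]], u)
    system$events$catalysts[[i]] <- setdiff(system$events$catalysts[[i]], u)
    system$events$inhibitors[[i]] <- setdiff(system$events$inhibitors[[i]], u)
  } else {
    # event u -> signal v: derivation membership
    system <- remove_output_membership(system, u, v)
  }
  system
}
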