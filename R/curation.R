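# Dependency-graph construction, SCC detection, and the two
# biologically-motivated loop fixes (catalysis, complex dissociation).
# Loops in the Boolean system are self-justifying: once an output inside a
# cycle is fixed active, the cycle can sustain itself without any system
# input, so Minimum Input under-reports. Curation removes the statement
# memberships that create such cycles.

#' Build the dependency graph of a Boolean system
#'
#' One node per variable (signal and reaction); a directed edge `(u, v)`
#' exists iff some statement has `u` in its antecedent (positively or
#' negatively — inhibitors also sit on the left of the implication) and `v`
#' as its consequent.
#'
#' @param system A `boolean_system`.
#' @return An [igraph::igraph] with vertex attributes `name` (variable id),
#'   `label` (display name) and `class` (`"signal"` or `"reaction"`).
#' @export
dependency_graph <- function(system) {
  stopifnot(inherits(system, "boolean_system"))
  vars <- variables(system)
  edges <- purrr::map_dfr(statements(system), function(st) {
    ante <- c(st$pos, st$neg)
    if (length(ante) == 0L) return(NULL)
    tibble::tibble(from = ante, to = st$consequent)
  })
  edges <- dplyr::distinct(dplyr::arrange(edges, .data$from, .data$to))
  g <- igraph::make_empty_graph(n = length(vars), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = vars)
  labels <- c(system$signals$name,
              system$events$id)[match(vars, c(system$signals$id, system$events$id))]
  g <- igraph::set_vertex_attr(g, "label", value = labels)
  g <- igraph::set_vertex_attr(
    g, "class",
    value = ifelse(vars %in% system$events$id, "reaction", "signal"))
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges$from, edges$to))
  }
  g
}

as_dependency_graph <- function(x) {
  if (inherits(x, "boolean_system")) dependency_graph(x)
  else if (igraph::is_igraph(x)) x
  else rlang::abort("expected a boolean_system or igraph")
}

#' Find the nontrivial strongly connected components of a system
#'
#' Detects all maximal SCCs of order >= 2 (plus any singleton carrying a
#' self-edge) and classifies each as `catalysis` (order-2 signal/reaction
#' pair where the signal is both input and output of the reaction),
#' `complex-dissociation` (complex formation / modification / dissociation
#' cycle in which the dissociation recycles a reactant), or `other`.
#'
#' @param x A `boolean_system` or dependency graph.
#' @return An object of class `scc_report`: tibble with list-column
#'   `component` (sorted member ids), `order` and `classification`, ordered
#'   by smallest member id.
#' @export
find_sccs <- function(x) {
  g <- as_dependency_graph(x)
  comp <- igraph::components(g, mode = "strong")
  nodes <- igraph::V(g)$name
  groups <- split(nodes, comp$membership)
  loops <- igraph::which_loop(g)
  selfloop <- if (any(loops)) {
    unique(igraph::ends(g, igraph::E(g))[loops, 1L])
  } else character()
  keep <- vapply(groups, function(m) {
    length(m) >= 2L || any(m %in% selfloop)
  }, TRUE)
  groups <- lapply(unname(groups[keep]), sort)
  groups <- groups[order(vapply(groups, `[`, "", 1L))]
  cls <- vapply(groups, function(m) classify_scc(g, m), "")
  structure(tibble::tibble(component = groups,
                           order = lengths(groups),
                           classification = cls),
            class = c("scc_report", "tbl_df", "tbl", "data.frame"))
}

node_class <- function(g, v) {
  igraph::vertex_attr(g, "class", v)
}

classify_scc <- function(g, members) {
  classes <- node_class(g, members)
  if (length(members) == 2L && setequal(classes, c("signal", "reaction"))) {
    s <- members[classes == "signal"]
    r <- members[classes == "reaction"]
    both <- igraph::are_adjacent(g, s, r) && igraph::are_adjacent(g, r, s)
    if (both) return("catalysis")
  }
  if (nrow(dissociation_candidates(g, members)) > 0L) {
    return("complex-dissociation")
  }
  "other"
}

# Candidate (event, recycled signal) pairs for the dissociation fix: an
# event in the SCC that outputs a signal inside the SCC (the recycled
# reactant) while also producing something outside it (the modified
# product), in an SCC that contains a complex-formation event (>= 2
# incoming signals).
dissociation_candidates <- function(g, members) {
  classes <- node_class(g, members)
  reactions <- members[classes == "reaction"]
  if (length(reactions) == 0L) return(tibble::tibble(event = character(),
                                                     signal = character()))
  formation <- any(vapply(reactions, function(r) {
    length(igraph::neighbors(g, r, mode = "in")) >= 2L
  }, TRUE))
  if (!formation) return(tibble::tibble(event = character(), signal = character()))
  purrr::map_dfr(reactions, function(r) {
    succ <- igraph::V(g)$name[igraph::neighbors(g, r, mode = "out")]
    inside <- intersect(succ, members)
    outside <- setdiff(succ, members)
    if (length(inside) == 0L || length(outside) == 0L) return(NULL)
    tibble::tibble(event = r, signal = sort(inside))
  })
}

curation_log_append <- function(system, kind, event, signal, note) {
  log <- curation_log(system)
  attr(system, "curation_log") <- dplyr::bind_rows(
    log, tibble::tibble(kind = kind, event = event, signal = signal, note = note))
  system
}

#' Curation actions recorded on a system
#' @param system A `boolean_system`.
#' @return Tibble with columns `kind`, `event`, `signal`, `note`.
#' @export
curation_log <- function(system) {
  log <- attr(system, "curation_log")
  if (is.null(log)) {
    log <- tibble::tibble(kind = character(), event = character(),
                          signal = character(), note = character())
  }
  log
}

#' Resolve a catalysis loop: remove the catalyst from the event outputs
#'
#' An order-2 SCC of the form signal `C` <-> reaction `r` arises when a
#' catalyst is written as both input and output of the reaction it
#' catalyses. The fix removes `C` from the outputs of `r`; `C` remains a
#' required input.
#'
#' @param system A `boolean_system`.
#' @param component Character vector: the two member ids of the SCC.
#' @return The curated system; the action is recorded in [curation_log()].
#' @export
apply_catalysis_fix <- function(system, component) {
  stopifnot(inherits(system, "boolean_system"))
  g <- dependency_graph(system)
  component <- sort(unique(component))
  if (length(component) != 2L ||
      classify_scc(g, component) != "catalysis") {
    rlang::abort("component does not match the catalysis motif (order-2 SCC with the catalyst both input and output)",
                 class = "boolsig_motif_mismatch")
  }
  classes <- node_class(g, component)
  cat_sig <- component[classes == "signal"]
  ev <- component[classes == "reaction"]
  system <- remove_output_membership(system, ev, cat_sig)
  system <- curation_log_append(system, "remove-catalyst-output", ev, cat_sig,
                                "catalysis SCC: catalyst removed from event outputs")
  recompile(system)
}

remove_output_membership <- function(system, event_id, signal_id) {
  i <- match(event_id, system$events$id)
  outs <- setdiff(system$events$outputs[[i]], signal_id)
  if (length(outs) == 0L) {
    rlang::abort(sprintf("removing '%s' would leave event '%s' with no outputs",
                         signal_id, event_id),
                 class = "boolsig_invalid_event")
  }
  system$events$outputs[[i]] <- outs
  system
}

#' Resolve a complex-dissociation loop: stop recycling the reactant
#'
#' In the formation/modification/dissociation motif, a complex forms from a
#' reactant and a partner, is modified, and dissociates to yield the
#' modified product plus the recycled reactant. The recycling edge lets the
#' cycle justify itself, so a target inside it appears achievable without
#' the reactant's own upstream input. The fix removes the recycled reactant
#' from the dissociation event's outputs, keeping the modified product
#' derivable while still requiring the reactant for complex formation.
#' (Deleting the formation edge instead would allow the complex to form
#' without the reactant, which is wrong.)
#'
#' @param system A `boolean_system`.
#' @param component Character vector of SCC member ids.
#' @param recycled Optional named pair `c(event = ..., signal = ...)`
#'   selecting which candidate to cut when the motif is ambiguous
#'   (semi-automatic contract: ambiguity is an error listing the candidates).
#' @return The curated system; the action is recorded in [curation_log()].
#' @export
apply_dissociation_fix <- function(system, component, recycled = NULL) {
  stopifnot(inherits(system, "boolean_system"))
  g <- dependency_graph(system)
  component <- sort(unique(component))
  cand <- dissociation_candidates(g, component)
  if (nrow(cand) == 0L) {
    rlang::abort("component does not match the complex-dissociation motif",
                 class = "boolsig_motif_mismatch")
  }
  if (!is.null(recycled)) {
    hit <- cand$event == recycled[["event"]] & cand$signal == recycled[["signal"]]
    if (!any(hit)) {
      rlang::abort("requested (event, signal) pair is not a candidate recycled reactant",
                   class = "boolsig_motif_mismatch")
    }
    cand <- cand[hit, , drop = FALSE]
  } else if (nrow(cand) > 1L) {
    rlang::abort(
      sprintf("ambiguous dissociation motif; pick `recycled` among: %s",
              paste(sprintf("(%s, %s)", cand$event, cand$signal), collapse = ", ")),
      class = "boolsig_ambiguous_motif", candidates = cand)
  }
  system <- remove_output_membership(system, cand$event[1L], cand$signal[1L])
  system <- curation_log_append(system, "remove-derivation-membership",
                                cand$event[1L], cand$signal[1L],
                                "dissociation SCC: recycled reactant removed from event outputs")
  recompile(system)
}

#' Apply all unambiguous automatic loop fixes
#'
#' Repeatedly detects SCCs and applies the catalysis fix to catalysis
#' components and the dissociation fix to unambiguous dissociation
#' components. Stops when no nontrivial SCC remains or only components
#' requiring manual curation (ambiguous or `other`) are left; those are
#' returned for resolution via the GML round trip.
#'
#' @param system A `boolean_system`.
#' @param max_passes Safety bound on detection/fix passes.
#' @return The curated system; components left for manual curation are in
#'   the `unresolved` attribute (an `scc_report`).
#' @export
curate_sccs <- function(system, max_passes = 100L) {
  for (pass in seq_len(max_passes)) {
    report <- find_sccs(system)
    if (nrow(report) == 0L) break
    acted <- FALSE
    for (k in seq_len(nrow(report))) {
      comp <- report$component[[k]]
      if (report$classification[k] == "catalysis") {
        system <- apply_catalysis_fix(system, comp)
        acted <- TRUE
        break
      }
      if (report$classification[k] == "complex-dissociation") {
        fixed <- tryCatch(apply_dissociation_fix(system, comp),
                          boolsig_ambiguous_motif = function(e) NULL)
        if (!is.null(fixed)) {
          system <- fixed
          acted <- TRUE
          break
        }
      }
    }
    if (!acted) break
  }
  attr(system, "unresolved") <- find_sccs(system)
  system
}

#' Whole-graph topology statistics
#'
#' Order and size count all nodes/edges. Degree maxima, source and sink
#' counts are taken over signal nodes (a source is a signal with no incoming
#' dependency edge and at least one outgoing; a sink the reverse). Path
#' statistics treat the graph as directed and ignore unreachable pairs;
#' the characteristic path length is the mean finite shortest-path length
#' over ordered non-self pairs, and the radius is the minimum positive
#' eccentricity over nodes that reach at least one other node.
#'
#' @param x A `boolean_system` or dependency graph.
#' @return A one-row tibble with columns `order`, `size`, `max_indegree`,
#'   `max_outdegree`, `n_sinks`, `n_sources`, `n_scc`,
#'   `avg_neighbours`, `char_path_length`, `diameter`, `radius`.
#' @export
graph_statistics <- function(x) {
  g <- as_dependency_graph(x)
  n <- igraph::vcount(g)
  sig <- igraph::V(g)$name[igraph::V(g)$class == "signal"]
  din <- igraph::degree(g, v = sig, mode = "in")
  dout <- igraph::degree(g, v = sig, mode = "out")
  d <- igraph::distances(g, mode = "out")
  diag(d) <- Inf
  finite <- is.finite(d)
  ecc <- apply(d, 1L, function(row) {
    f <- row[is.finite(row)]
    if (length(f)) max(f) else NA_real_
  })
  nbrs <- vapply(seq_len(n), function(v) {
    length(unique(setdiff(
      as.integer(igraph::neighbors(g, v, mode = "all")), v)))
  }, 0L)
  tibble::tibble(
    order = n,
    size = igraph::ecount(g),
    max_indegree = if (length(din)) max(din) else 0L,
    max_outdegree = if (length(dout)) max(dout) else 0L,
    n_sinks = sum(dout == 0L & din > 0L),
    n_sources = sum(din == 0L & dout > 0L),
    n_scc = nrow(find_sccs(g)),
    avg_neighbours = mean(nbrs),
    char_path_length = if (any(finite)) mean(d[finite]) else NA_real_,
    diameter = if (any(finite)) max(d[finite]) else NA_real_,
    radius = if (any(!is.na(ecc) & ecc > 0)) min(ecc[!is.na(ecc) & ecc > 0])
             else NA_real_)
}

#' Plot the dependency graph of a system
#'
#' Hypergraph-style layout: square reaction nodes link their participant
#' signals, mirroring biochemical diagrams.
#'
#' @param object A `boolean_system`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.boolean_system <- function(object, ...) {
  g <- dependency_graph(object)
  set.seed(1L)  # layout reproducibility only
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(name = igraph::V(g)$name,
                          class = igraph::V(g)$class,
                          x = xy[, 1L], y = xy[, 2L])
  el <- igraph::as_edgelist(g)
  edges <- tibble::tibble(
    x = nodes$x[match(el[, 1L], nodes$name)],
    y = nodes$y[match(el[, 1L], nodes$name)],
    xend = nodes$x[match(el[, 2L], nodes$name)],
    yend = nodes$y[match(el[, 2L], nodes$name)])
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey60",
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$class,
                   colour = .data$class), size = 3) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
      vjust = -1, size = 3) +
    ggplot2::scale_shape_manual(values = c(signal = 16, reaction = 15)) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
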