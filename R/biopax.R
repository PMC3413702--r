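# BioPAX Level 3 OWL input via xml2. The mapping from BioPAX classes to
# signalling events:
#   Conversion subclasses (BiochemicalReaction, ComplexAssembly, Transport,
#     TransportWithBiochemicalReaction, Degradation) -> one event; `left`
#     participants become inputs, `right` participants outputs.
#   Catalysis with an activating controlType -> controller joins the
#     conjunctive inputs of the controlled reaction.
#   Control/Modulation with an inhibitory controlType -> if it controls a
#     reaction, an event-specific inhibitor of that reaction; if it controls
#     a Catalysis, by default an event-specific inhibitor of the catalysed
#     reaction (mechanistic reading); with `modulation = "general"`, a
#     general inhibition of each output of that reaction.
#   Complex -> one signal identified by its component multiset (components
#     sorted and joined with ":"), so identical complexes from different
#     records collapse to one variable.
# The control-type vocabulary is configurable via `activation_types` /
# `inhibition_types` because database exports differ (e.g.
# "ACTIVATION-ALLOSTERIC").

BP_CONVERSION_CLASSES <- c("BiochemicalReaction", "ComplexAssembly",
                           "Transport", "TransportWithBiochemicalReaction",
                           "Degradation", "Conversion")

#' Read a BioPAX Level 3 OWL file into a Boolean system
#'
#' @param path Path to an RDF/XML BioPAX Level 3 file.
#' @param modulation How to interpret inhibitory controls of a catalysis:
#'   `"event"` (default; inhibitor of the catalysed reaction) or
#'   `"general"` (general inhibition of the reaction's outputs).
#' @param activation_types,inhibition_types Control-type vocabulary prefixes
#'   treated as activating/inhibitory.
#' @param exclude Character vector of entity or interaction ids to drop
#'   (e.g. a user-supplied exclusion list for amalgamated databases).
#' @return A compiled `boolean_system` with signal metadata (names, unification
#'   xrefs) carried through.
#' @export
read_biopax <- function(path, modulation = c("event", "general"),
                        activation_types = "ACTIVATION",
                        inhibition_types = "INHIBITION",
                        exclude = character()) {
  modulation <- match.arg(modulation)
  doc <- xml2::read_xml(path)
  ns_defs <- xml2::xml_ns(doc)
  bp_uri <- ns_defs[grepl("biopax-level", ns_defs)]
  if (length(bp_uri) == 0L) {
    rlang::abort("file does not declare a BioPAX namespace",
                 class = "boolsig_biopax_error")
  }
  if (!any(grepl("biopax-level3", bp_uri))) {
    rlang::abort(sprintf("unsupported BioPAX level (namespace %s); only Level 3 is supported",
                         bp_uri[1]),
                 class = "boolsig_biopax_error")
  }
  ns <- c(bp = unname(bp_uri[grepl("biopax-level3", bp_uri)][1]),
          rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#")

  node_id <- function(node) {
    id <- xml2::xml_attr(node, "ID")
    if (is.na(id)) id <- xml2::xml_attr(node, "about")
    sub("^.*#", "", id)
  }
  ref_of <- function(node) {
    r <- xml2::xml_attr(node, "resource")
    if (length(r) == 0 || is.na(r)) NA_character_ else sub("^.*#", "", r)
  }
  text_or_na <- function(node, xp) {
    v <- xml2::xml_find_first(node, xp, ns)
    if (inherits(v, "xml_missing")) NA_character_ else xml2::xml_text(v)
  }

  # --- physical entities ----------------------------------------------------
  ent_nodes <- xml2::xml_find_all(doc, paste0(
    "//bp:Protein | //bp:SmallMolecule | //bp:Rna | //bp:Dna | ",
    "//bp:PhysicalEntity | //bp:Complex"), ns)
  entities <- list()
  for (nd in ent_nodes) {
    id <- node_id(nd)
    if (is.na(id) || id %in% exclude) next
    nm <- text_or_na(nd, "./bp:displayName | ./bp:standardName | ./bp:name")
    comps <- vapply(xml2::xml_find_all(nd, "./bp:component", ns), ref_of, "")
    entities[[id]] <- list(id = id, name = if (is.na(nm)) id else nm,
                           components = comps[!is.na(comps)])
  }
  # resolve complexes to component-multiset signal ids (components may
  # themselves be complexes; resolve recursively with a depth guard)
  resolve_signal <- function(id, depth = 0L) {
    ent <- entities[[id]]
    if (is.null(ent)) return(NA_character_)
    if (length(ent$components) == 0L || depth > 20L) return(ent$id)
    parts <- vapply(ent$components, resolve_signal, "", depth = depth + 1L)
    if (anyNA(parts)) return(NA_character_)
    paste(sort(parts), collapse = ":")
  }
  signal_id <- stats::setNames(
    vapply(names(entities), resolve_signal, ""), names(entities))
  signal_name <- vapply(names(entities), function(id) {
    ent <- entities[[id]]
    if (length(ent$components) == 0L) return(ent$name)
    parts <- vapply(ent$components, function(c2) {
      if (!is.null(entities[[c2]])) entities[[c2]]$name else c2
    }, "")
    paste(sort(parts), collapse = ":")
  }, "")

  participants <- function(node, xp) {
    refs <- vapply(xml2::xml_find_all(node, xp, ns), ref_of, "")
    refs <- refs[!is.na(refs)]
    mapped <- signal_id[refs]
    dangling <- refs[is.na(mapped) | is.na(names(mapped))]
    dangling <- c(dangling, refs[!refs %in% names(signal_id)])
    if (length(dangling)) {
      rlang::warn(sprintf("skipping dangling participant reference(s): %s",
                          paste(unique(dangling), collapse = ", ")))
    }
    unique(mapped[!is.na(mapped)])
  }

  # --- conversions -> events ------------------------------------------------
  conv_xp <- paste(sprintf("//bp:%s", BP_CONVERSION_CLASSES), collapse = " | ")
  conv_nodes <- xml2::xml_find_all(doc, conv_xp, ns)
  events <- list()
  for (nd in conv_nodes) {
    id <- node_id(nd)
    if (is.na(id) || id %in% exclude) next
    ins <- participants(nd, "./bp:left")
    outs <- participants(nd, "./bp:right")
    if (length(outs) == 0L) {
      rlang::warn(sprintf("skipping reaction '%s' with no resolvable outputs", id))
      next
    }
    events[[id]] <- list(id = id, inputs = ins, outputs = outs,
                         inhibitors = character(), catalysts = character())
  }

  # --- controls -------------------------------------------------------------
  ctrl_nodes <- xml2::xml_find_all(
    doc, "//bp:Catalysis | //bp:Control | //bp:Modulation", ns)
  catalysis_target <- character()  # catalysis id -> controlled reaction id
  general_inh <- list()
  is_type <- function(ct, prefixes) {
    !is.na(ct) && any(startsWith(ct, prefixes))
  }
  # first pass: catalysis (so modulation can point at it)
  for (nd in ctrl_nodes) {
    if (xml2::xml_name(nd) != "Catalysis") next
    id <- node_id(nd)
    if (id %in% exclude) next
    ct <- text_or_na(nd, "./bp:controlType")
    if (is.na(ct)) ct <- "ACTIVATION"
    ctl_ref <- ref_of(xml2::xml_find_first(nd, "./bp:controlled", ns))
    ctrlr <- participants(nd, "./bp:controller")
    if (is.na(ctl_ref) || is.null(events[[ctl_ref]])) {
      rlang::warn(sprintf("skipping catalysis '%s' with dangling controlled reference", id))
      next
    }
    if (is_type(ct, activation_types)) {
      events[[ctl_ref]]$catalysts <-
        unique(c(events[[ctl_ref]]$catalysts, ctrlr))
      catalysis_target[id] <- ctl_ref
    } else if (is_type(ct, inhibition_types)) {
      events[[ctl_ref]]$inhibitors <-
        unique(c(events[[ctl_ref]]$inhibitors, ctrlr))
    }
  }
  for (nd in ctrl_nodes) {
    if (xml2::xml_name(nd) == "Catalysis") next
    id <- node_id(nd)
    if (id %in% exclude) next
    ct <- text_or_na(nd, "./bp:controlType")
    ctl_ref <- ref_of(xml2::xml_find_first(nd, "./bp:controlled", ns))
    ctrlr <- participants(nd, "./bp:controller")
    if (is.na(ctl_ref) || length(ctrlr) == 0L) {
      rlang::warn(sprintf("skipping control '%s' with dangling references", id))
      next
    }
    target_event <- if (!is.null(events[[ctl_ref]])) ctl_ref
                    else unname(catalysis_target[ctl_ref])
    if (is.null(target_event) || is.na(target_event)) {
      rlang::warn(sprintf("skipping control '%s': controlled '%s' not found",
                          id, ctl_ref))
      next
    }
    if (is_type(ct, inhibition_types)) {
      if (modulation == "general") {
        for (out in events[[target_event]]$outputs) {
          for (i in ctrlr) {
            general_inh[[length(general_inh) + 1L]] <-
              list(inhibitor = i, target = out)
          }
        }
      } else {
        events[[target_event]]$inhibitors <-
          unique(c(events[[target_event]]$inhibitors, ctrlr))
      }
    } else if (is_type(ct, activation_types)) {
      events[[target_event]]$catalysts <-
        unique(c(events[[target_event]]$catalysts, ctrlr))
    }
  }

  if (length(events) == 0L) {
    return(boolean_system(as_events(tibble::tibble(
      id = character(), inputs = list(), outputs = list()))))
  }
  ev_tbl <- purrr::map_dfr(events[order(names(events))], function(e) {
    signalling_event(e$id, e$inputs, e$outputs, e$inhibitors, e$catalysts)
  })
  gi_tbl <- if (length(general_inh)) purrr::map_dfr(general_inh, tibble::as_tibble)
            else NULL
  used <- sort(unique(unname(signal_id[!is.na(signal_id)])))
  sig_tbl <- tibble::tibble(
    id = used,
    name = signal_name[match(used, signal_id)],
    xrefs = rep(list(character()), length(used)))
  boolean_system(ev_tbl, general_inhibitions = gi_tbl, signals = sig_tbl)
}
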