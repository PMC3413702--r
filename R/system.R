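#' Compile signalling events into a Boolean statement system
#'
#' Builds the central model object: every signal is in bijection with a binary
#' signal variable, every event gets a dedicated reaction variable, and the
#' event list is compiled into two families of Boolean statements. An
#' event-activation statement ties a reaction variable to the conjunction of
#' its required inputs and the negation of its inhibitors; an
#' output-derivation statement ties each produced signal to the disjunction
#' of the reactions producing it. Both families are interpreted as
#' equivalences when encoded (see [to_cnf()]): a reaction fires exactly when
#' its condition holds, and a signal is active exactly when at least one
#' producing reaction fires. Inhibition acts at the event level only —
#' an inhibitor prevents specific events from firing, it never deactivates a
#' signal directly, so activator and inhibitor can co-occur without creating
#' an infeasible state.
#'
#' @param events Event table from [signalling_event()] / [as_events()] rows.
#' @param general_inhibitions Optional data frame with columns `inhibitor`,
#'   `target`: the inhibitor blocks signalling *by* `target`, so it is
#'   attached as an inhibitor to every event producing `target`.
#' @param signals Optional tibble of signal metadata with columns `id`,
#'   `name` (and optionally a list-column `xrefs` of "db:accession" strings);
#'   ids not mentioned by any event are kept and reported as isolated.
#' @return An object of class `boolean_system`.
#' @examples
#' sys <- boolean_system(signalling_event("e1", "S1", "S2", inhibitors = "I"))
#' statements(sys)
#' classify_signals(sys)
#' @export
boolean_system <- function(events, general_inhibitions = NULL, signals = NULL) {
  events <- as_events(events)
  gi <- canonical_geninh(general_inhibitions)
  sig_ids <- sort(unique(c(
    unlist(events$inputs), unlist(events$outputs),
    unlist(events$inhibitors), unlist(events$catalysts),
    gi$inhibitor, gi$target,
    if (!is.null(signals)) as.character(signals$id)
  )))
  clash <- intersect(sig_ids, events$id)
  if (length(clash)) {
    rlang::abort(sprintf("id(s) used as both signal and event: %s",
                         paste(clash, collapse = ", ")),
                 class = "boolsig_id_clash")
  }
  overlap <- purrr::map2(events$inhibitors,
                         purrr::map2(events$inputs, events$catalysts, union),
                         intersect)
  bad <- lengths(overlap) > 0L
  if (any(bad)) {
    rlang::warn(sprintf(
      "signal(s) inhibiting an event they feed (event permanently inactive): %s",
      paste(sprintf("%s in %s", purrr::map_chr(overlap[bad], paste, collapse = "/"),
                    events$id[bad]), collapse = ", ")))
  }
  meta <- tibble::tibble(id = sig_ids, name = sig_ids,
                         xrefs = rep(list(character()), length(sig_ids)))
  if (!is.null(signals)) {
    signals <- tibble::as_tibble(signals)
    m <- match(meta$id, as.character(signals$id))
    hit <- !is.na(m)
    if ("name" %in% names(signals)) {
      nm <- as.character(signals$name)[m[hit]]
      meta$name[hit] <- ifelse(is.na(nm) | !nzchar(nm), meta$id[hit], nm)
    }
    if ("xrefs" %in% names(signals)) {
      meta$xrefs[hit] <- lapply(signals$xrefs[m[hit]], as.character)
    }
  }
  sys <- structure(
    list(signals = meta,
         events = events[order(events$id), , drop = FALSE],
         general_inhibitions = gi,
         statements = NULL),
    class = "boolean_system")
  sys <- materialize_general_inhibitions(sys)
  recompile(sys)
}

canonical_geninh <- function(general_inhibitions) {
  if (is.null(general_inhibitions) || NROW(general_inhibitions) == 0L) {
    return(tibble::tibble(inhibitor = character(), target = character()))
  }
  gi <- tibble::as_tibble(general_inhibitions)
  stopifnot(all(c("inhibitor", "target") %in% names(gi)))
  dplyr::distinct(dplyr::arrange(
    tibble::tibble(inhibitor = as.character(gi$inhibitor),
                   target = as.character(gi$target)),
    .data$inhibitor, .data$target))
}

# Fold every general inhibition (I blocks signalling by S) into the inhibitor
# set of each event producing S. Idempotent (set union).
materialize_general_inhibitions <- function(sys) {
  gi <- sys$general_inhibitions
  if (nrow(gi) == 0L) return(sys)
  for (k in seq_len(nrow(gi))) {
    producers <- which(purrr::map_lgl(sys$events$outputs, ~ gi$target[k] %in% .x))
    if (length(producers) == 0L) {
      rlang::warn(sprintf(
        "general inhibition of '%s' by '%s' targets a signal with no producers; ignored",
        gi$target[k], gi$inhibitor[k]))
      next
    }
    for (i in producers) {
      sys$events$inhibitors[[i]] <-
        sort(unique(c(sys$events$inhibitors[[i]], gi$inhibitor[k])))
    }
  }
  sys
}

recompile <- function(sys) {
  sys$statements <- compile_statements(sys$events)
  sys
}

#' Compile the Boolean statements for an event table
#'
#' Produces one event-activation statement per event (positive literals for
#' every required input, negative literals for every inhibitor, consequent =
#' the reaction variable) and exactly one output-derivation statement per
#' distinct produced signal (positive literals over all reactions producing
#' it). Statement count is therefore `|events| + |signals with >= 1 producer|`.
#'
#' @param events Canonical event table (see [as_events()]).
#' @return A list of statements, each a list with elements `kind`
#'   (`"event-activation"` or `"output-derivation"`), `consequent`, `pos`
#'   (positive-literal variables) and `neg` (negative-literal variables),
#'   sorted by consequent id within each kind.
#' @export
compile_statements <- function(events) {
  events <- as_events(events)
  acts <- lapply(seq_len(nrow(events)), function(i) {
    list(kind = "event-activation",
         consequent = events$id[i],
         pos = event_requirements(events, i),
         neg = sort(events$inhibitors[[i]]))
  })
  produced <- sort(unique(unlist(events$outputs)))
  ders <- lapply(produced, function(s) {
    prods <- events$id[purrr::map_lgl(events$outputs, ~ s %in% .x)]
    list(kind = "output-derivation", consequent = s,
         pos = sort(prods), neg = character())
  })
  acts <- acts[order(vapply(acts, `[[`, "", "consequent"))]
  c(acts, ders)
}

#' Extract the compiled statements of a system
#' @param system A `boolean_system`.
#' @return The statement list (see [compile_statements()]).
#' @export
statements <- function(system) {
  stopifnot(inherits(system, "boolean_system"))
  system$statements
}

#' All variable ids of a system (signals then events, each sorted)
#' @param system A `boolean_system`.
#' @return Character vector of variable ids.
#' @export
variables <- function(system) {
  stopifnot(inherits(system, "boolean_system"))
  c(system$signals$id, system$events$id)
}

#' Attach event-specific and general inhibitors to a compiled system
#'
#' Event-specific inhibitors become negative literals in that event's
#' activation statement only. A general inhibitor of a signal is attached to
#' every event producing that signal. The operation is idempotent and
#' independent inhibitions commute.
#'
#' @param system A `boolean_system`.
#' @param event_inhibitions Named list: event id -> character vector of
#'   inhibitor signal ids.
#' @param general_inhibitions Data frame with columns `inhibitor`, `target`.
#' @return The updated `boolean_system`.
#' @export
attach_inhibitors <- function(system, event_inhibitions = list(),
                              general_inhibitions = NULL) {
  stopifnot(inherits(system, "boolean_system"))
  known_sig <- system$signals$id
  if (length(event_inhibitions)) {
    miss <- setdiff(names(event_inhibitions), system$events$id)
    if (length(miss)) {
      rlang::abort(sprintf("unknown event id(s): %s", paste(miss, collapse = ", ")),
                   class = "boolsig_unknown_id")
    }
    badsig <- setdiff(unique(unlist(event_inhibitions)), known_sig)
    if (length(badsig)) {
      rlang::abort(sprintf("unknown inhibitor signal(s): %s",
                           paste(badsig, collapse = ", ")),
                   class = "boolsig_unknown_id")
    }
    for (eid in names(event_inhibitions)) {
      i <- match(eid, system$events$id)
      system$events$inhibitors[[i]] <-
        sort(unique(c(system$events$inhibitors[[i]],
                      as.character(event_inhibitions[[eid]]))))
    }
  }
  gi <- canonical_geninh(general_inhibitions)
  if (nrow(gi)) {
    badsig <- setdiff(unique(c(gi$inhibitor, gi$target)), known_sig)
    if (length(badsig)) {
      rlang::abort(sprintf("unknown signal(s) in general inhibitions: %s",
                           paste(badsig, collapse = ", ")),
                   class = "boolsig_unknown_id")
    }
    system$general_inhibitions <-
      dplyr::distinct(dplyr::bind_rows(system$general_inhibitions, gi))
    system$general_inhibitions <-
      dplyr::arrange(system$general_inhibitions, .data$inhibitor, .data$target)
    system <- materialize_general_inhibitions(sys = system)
  }
  recompile(system)
}

#' Partition the signals of a system into sources, sinks and internal nodes
#'
#' System inputs (sources) are signals consumed by at least one event —
#' as an input, catalyst or inhibitor — but produced by none; system outputs
#' (sinks) are produced but never consumed; internal nodes are both. Signals
#' declared in the metadata but touching no event are reported as isolated.
#'
#' @param system A `boolean_system`.
#' @return A list with sorted character vectors `sources`, `sinks`,
#'   `internal`, `isolated`.
#' @export
classify_signals <- function(system) {
  stopifnot(inherits(system, "boolean_system"))
  ev <- system$events
  input_side <- unique(c(unlist(ev$inputs), unlist(ev$catalysts),
                         unlist(ev$inhibitors)))
  output_side <- unique(unlist(ev$outputs))
  participating <- union(input_side, output_side)
  list(sources = sort(setdiff(input_side, output_side)),
       sinks = sort(setdiff(output_side, input_side)),
       internal = sort(intersect(input_side, output_side)),
       isolated = sort(setdiff(system$signals$id, participating)))
}

#' @export
print.boolean_system <- function(x, ...) {
  cls <- classify_signals(x)
  cat(sprintf("<boolean_system> %d signals, %d events, %d statements\n",
              nrow(x$signals), nrow(x$events), length(x$statements)))
  cat(sprintf("  inputs: %d  outputs: %d  internal: %d  general inhibitions: %d\n",
              length(cls$sources), length(cls$sinks), length(cls$internal),
              nrow(x$general_inhibitions)))
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-row summary of a Boolean system
#' @param x A `boolean_system`.
#' @param ... Unused.
#' @return A one-row tibble of counts.
#' @export
glance.boolean_system <- function(x, ...) {
  cls <- classify_signals(x)
  tibble::tibble(
    n_signals = nrow(x$signals), n_events = nrow(x$events),
    n_statements = length(x$statements),
    n_inputs = length(cls$sources), n_outputs = length(cls$sinks),
    n_internal = length(cls$internal),
    n_general_inhibitions = nrow(x$general_inhibitions))
}

#' Statements of a system as a tidy table
#' @param x A `boolean_system`.
#' @param ... Unused.
#' @return A tibble with one row per literal occurrence: `kind`,
#'   `consequent`, `variable`, `sign`.
#' @export
tidy.boolean_system <- function(x, ...) {
  purrr::map_dfr(statements(x), function(st) {
    n_lit <- length(st$pos) + length(st$neg)
    if (n_lit == 0L) {
      return(tibble::tibble(kind = st$kind, consequent = st$consequent,
                            variable = NA_character_, sign = NA_character_))
    }
    tibble::tibble(kind = st$kind, consequent = st$consequent,
                   variable = c(st$pos, st$neg),
                   sign = rep(c("positive", "negative"),
                              c(length(st$pos), length(st$neg))))
  })
}
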