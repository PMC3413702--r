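#' Construct a signalling event
#'
#' A signalling event is one reaction or transduction step: a conjunctive set
#' of required input signals (upstream signals, catalysts and activating
#' signals all behave identically and are required together), a non-empty set
#' of output signals it produces, and an optional set of event-specific
#' inhibitors, each of which blocks this event (and only this event) when
#' active.
#'
#' @param id Unique event identifier; must not collide with any signal id.
#' @param inputs Character vector of input signal ids (may be empty for a
#'   constitutive event).
#' @param outputs Character vector of output signal ids; must be non-empty.
#' @param inhibitors Character vector of signal ids inhibiting this event.
#' @param catalysts Character vector of catalyst signal ids; catalysts are
#'   required for the event and are merged into the conjunctive input set at
#'   compile time, but are kept separate so that text serialization round
#'   trips exactly.
#' @return A one-row tibble with list-columns `inputs`, `outputs`,
#'   `inhibitors`, `catalysts`; rows from several calls can be combined with
#'   [dplyr::bind_rows()] and fed to [boolean_system()].
#' @examples
#' ev <- signalling_event("e1", inputs = "S1", outputs = "S2", inhibitors = "I")
#' boolean_system(ev)
#' @export
signalling_event <- function(id, inputs = character(), outputs,
                             inhibitors = character(), catalysts = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  outputs <- as.character(outputs)
  if (length(outputs) == 0L) {
    rlang::abort(sprintf("event '%s' has an empty output set", id),
                 class = "boolsig_invalid_event")
  }
  tibble::tibble(
    id = id,
    inputs = list(sort(unique(as.character(inputs)))),
    outputs = list(sort(unique(outputs))),
    inhibitors = list(sort(unique(as.character(inhibitors)))),
    catalysts = list(sort(unique(as.character(catalysts))))
  )
}

#' Coerce a data frame of events to the canonical event table
#'
#' Accepts a data frame with columns `id`, `inputs`, `outputs` and optionally
#' `inhibitors`, `catalysts`. Set-valued columns may be list-columns of
#' character vectors or comma-separated strings.
#'
#' @param x A data frame describing one event per row.
#' @return A tibble in the canonical event layout used by [boolean_system()].
#' @export
as_events <- function(x) {
  stopifnot(is.data.frame(x), all(c("id", "inputs", "outputs") %in% names(x)))
  split_col <- function(col) {
    if (is.list(col)) {
      lapply(col, function(v) sort(unique(as.character(v[!is.na(v) & nzchar(v)]))))
    } else {
      lapply(as.character(col), function(s) {
        if (is.na(s) || !nzchar(s)) return(character())
        sort(unique(trimws(strsplit(s, ",", fixed = TRUE)[[1]])))
      })
    }
  }
  out <- tibble::tibble(
    id = as.character(x$id),
    inputs = split_col(x$inputs),
    outputs = split_col(x$outputs),
    inhibitors = if ("inhibitors" %in% names(x)) split_col(x$inhibitors)
                 else rep(list(character()), nrow(x)),
    catalysts = if ("catalysts" %in% names(x)) split_col(x$catalysts)
                else rep(list(character()), nrow(x))
  )
  if (anyDuplicated(out$id)) {
    rlang::abort(sprintf("duplicate event id(s): %s",
                         paste(unique(out$id[duplicated(out$id)]), collapse = ", ")),
                 class = "boolsig_duplicate_event")
  }
  empty <- lengths(out$outputs) == 0L
  if (any(empty)) {
    rlang::abort(sprintf("event(s) with empty output set: %s",
                         paste(out$id[empty], collapse = ", ")),
                 class = "boolsig_invalid_event")
  }
  out
}

# effective conjunctive input set of one event row (inputs + catalysts)
event_requirements <- function(events, i) {
  sort(unique(c(events$inputs[[i]], events$catalysts[[i]])))
}
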