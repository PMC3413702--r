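# Deterministic model generators: the two worked toy systems (inhibition,
# complex-dissociation loop) and random layered signalling systems with
# exactly known cycle content for property tests.

#' The two-signal inhibition toy model
#'
#' One event transduces `S1` to `S2` and is blocked by the event-specific
#' inhibitor `I`. This is the minimal system exhibiting the event-level
#' inhibition semantics: `S1` active and `I` inactive yields `S2`; absence
#' of the inhibitor alone does not activate `S2`; and simultaneous presence
#' of activator and inhibitor leaves the system feasible with `S2` inactive.
#'
#' @return A `boolean_system` with variables `S1`, `S2`, `I`, `e1`.
#' @export
toy_inhibition_model <- function() {
  boolean_system(signalling_event("e1", inputs = "S1", outputs = "S2",
                                  inhibitors = "I"))
}

#' The complex-dissociation loop toy model
#'
#' `I` produces `X`; `X` and `J` form the complex `X:J`; the complex is
#' converted to `X:J'`; dissociation yields `X` and the modified product
#' `J'`. Uncurated, the recycling of `X` creates a strongly connected
#' component that lets `J'` be produced from `J` alone (the loop justifies
#' itself). With `curated = TRUE` the dissociation fix is applied (the
#' recycled `X` is removed from the dissociation outputs), after which both
#' `I` and `J` are required to activate `J'`.
#'
#' @param curated Apply the dissociation fix (default `FALSE`).
#' @return A `boolean_system` with 6 signals and 4 events.
#' @export
toy_loop_model <- function(curated = FALSE) {
  sys <- boolean_system(dplyr::bind_rows(
    signalling_event("r_X", inputs = "I", outputs = "X"),
    signalling_event("r_complex", inputs = c("X", "J"), outputs = "X:J"),
    signalling_event("r_convert", inputs = "X:J", outputs = "X:J'"),
    signalling_event("r_dissoc", inputs = "X:J'", outputs = c("X", "J'"))))
  if (curated) {
    scc <- find_sccs(sys)
    stopifnot(nrow(scc) == 1L)
    sys <- apply_dissociation_fix(sys, scc$component[[1L]])
  }
  sys
}

#' The MEK/ERK phosphorylation motif
#'
#' Active MEK and ERK form a complex in which MEK acts catalytically; the
#' complex dissociates post-phosphorylation to phosphorylated ERK plus
#' recycled MEK. The recycling edge creates the same dissociation-loop SCC
#' as [toy_loop_model()].
#'
#' @param curated Apply the dissociation fix (default `FALSE`).
#' @return A `boolean_system`.
#' @export
mek_erk_model <- function(curated = FALSE) {
  sys <- boolean_system(dplyr::bind_rows(
    signalling_event("r_actM", inputs = "upstream_MEK", outputs = "MEK"),
    signalling_event("r_actE", inputs = "upstream_ERK", outputs = "ERK"),
    signalling_event("r_complex", inputs = c("MEK", "ERK"), outputs = "MEK:ERK"),
    signalling_event("r_dissoc", inputs = "MEK:ERK", outputs = c("pERK", "MEK"))))
  if (curated) {
    scc <- find_sccs(sys)
    stopifnot(nrow(scc) == 1L)
    sys <- apply_dissociation_fix(sys, scc$component[[1L]])
  }
  sys
}

#' Specification for a random signalling system
#'
#' The generator builds a layered acyclic system: events draw their
#' conjunctive inputs from signals already available (system inputs first,
#' then earlier products) and produce new or later-ranked signals, so the
#' only cycles present are the planted motifs, whose count is exact ground
#' truth for SCC tests. Defaults are calibrated to the size of typical
#' randomly generated benchmark networks in this field (~150 signals, 50
#' events).
#'
#' @param n_inputs Number of dedicated input signals (default 50).
#' @param n_internal Upper bound on non-input signals created (default 100).
#' @param n_events Number of random events (default 50).
#' @param max_inputs_per_event Maximum conjunctive inputs per event
#'   (default 3).
#' @param p_inhibit Probability an event gains an event-specific inhibitor
#'   drawn from the input pool (default 0.2).
#' @param acyclic Must currently be `TRUE`; cycles enter only via planted
#'   motifs.
#' @param planted_catalysis Number of catalysis loops planted (default 0).
#' @param planted_dissociation Number of complex-dissociation loops planted
#'   (default 0).
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_inputs = 50L, n_internal = 100L, n_events = 50L,
                         max_inputs_per_event = 3L, p_inhibit = 0.2,
                         acyclic = TRUE, planted_catalysis = 0L,
                         planted_dissociation = 0L, seed = 1L) {
  stopifnot(n_inputs >= 0, n_internal >= 0, n_events >= 0,
            max_inputs_per_event >= 1, p_inhibit >= 0, p_inhibit <= 1,
            isTRUE(acyclic), planted_catalysis >= 0,
            planted_dissociation >= 0, seed == floor(seed))
  if (n_events > 0L && n_inputs == 0L) {
    rlang::abort("events demand inputs but the spec has no input signals",
                 class = "boolsig_invalid_spec")
  }
  structure(list(n_inputs = as.integer(n_inputs),
                 n_internal = as.integer(n_internal),
                 n_events = as.integer(n_events),
                 max_inputs_per_event = as.integer(max_inputs_per_event),
                 p_inhibit = p_inhibit, acyclic = TRUE,
                 planted_catalysis = as.integer(planted_catalysis),
                 planted_dissociation = as.integer(planted_dissociation),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a random signalling system from a spec
#'
#' @param spec A [fixture_spec()].
#' @return A `boolean_system`; identical spec (including seed) gives a
#'   byte-identical serialization.
#' @export
random_system <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    inputs <- sprintf("I%02d", seq_len(spec$n_inputs))
    rank <- stats::setNames(rep(0L, length(inputs)), inputs)
    internal_pool <- sprintf("S%03d", seq_len(spec$n_internal))
    next_internal <- 1L
    events <- vector("list", spec$n_events)
    for (k in seq_len(spec$n_events)) {
      avail <- names(rank)
      n_in <- sample.int(min(spec$max_inputs_per_event, length(avail)), 1L)
      ins <- sample(avail, n_in)
      max_rank <- max(rank[ins])
      # reuse a later-ranked existing signal as output sometimes, so some
      # signals gain multiple producers (redundancy for MIS diversity)
      reusable <- names(rank)[rank > max_rank & !(names(rank) %in% inputs)]
      if (length(reusable) && stats::runif(1) < 0.3) {
        out <- sample(reusable, 1L)
      } else if (next_internal <= length(internal_pool)) {
        out <- internal_pool[next_internal]
        next_internal <- next_internal + 1L
        rank[out] <- max_rank + 1L
      } else {
        later <- names(rank)[rank > max_rank]
        if (length(later)) {
          out <- sample(later, 1L)
        } else {  # pool exhausted, nothing reusable: overflow the pool
          out <- sprintf("S%03d", next_internal)
          next_internal <- next_internal + 1L
          rank[out] <- max_rank + 1L
        }
      }
      inh <- character()
      if (stats::runif(1) < spec$p_inhibit) {
        pool <- setdiff(inputs, ins)
        if (length(pool)) inh <- sample(pool, 1L)
      }
      events[[k]] <- signalling_event(sprintf("e%03d", k), ins, out, inh)
    }
    events <- dplyr::bind_rows(events)
    events <- dplyr::bind_rows(
      events,
      planted_motif_events(spec$planted_catalysis, spec$planted_dissociation))
    boolean_system(events)
  })
}

planted_motif_events <- function(n_cat, n_dis) {
  rows <- list()
  for (m in seq_len(n_cat)) {
    pre <- sprintf("cat%02d", m)
    rows[[length(rows) + 1L]] <- signalling_event(
      paste0(pre, "_e"),
      inputs = c(paste0(pre, "_C"), paste0(pre, "_A")),
      outputs = c(paste0(pre, "_C"), paste0(pre, "_Y")))
  }
  for (m in seq_len(n_dis)) {
    pre <- sprintf("dis%02d", m)
    rows[[length(rows) + 1L]] <- dplyr::bind_rows(
      signalling_event(paste0(pre, "_rX"), paste0(pre, "_I"), paste0(pre, "_X")),
      signalling_event(paste0(pre, "_rC"),
                       c(paste0(pre, "_X"), paste0(pre, "_J")),
                       paste0(pre, "_XJ")),
      signalling_event(paste0(pre, "_rM"), paste0(pre, "_XJ"), paste0(pre, "_XJp")),
      signalling_event(paste0(pre, "_rD"), paste0(pre, "_XJp"),
                       c(paste0(pre, "_X"), paste0(pre, "_Jp"))))
  }
  if (length(rows)) dplyr::bind_rows(rows) else NULL
}
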