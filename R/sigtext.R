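# SIGTXT: the package's plain-text signalling-event interchange format.
#
#   # comment
#   SIGNAL <id> [NAME <label>] [XREF <db>:<acc>]...
#   EVENT <id> IN <id>[,<id>...] OUT <id>[,<id>...] [INH <id>[,...]] [CAT <id>[,...]]
#   GENINH <inhibitor-id> OF <signal-id>
#
# Ids containing whitespace are double-quoted. Line order never changes the
# resulting system; serialization is canonical so parse(serialize(x)) = x.

sig_quote <- function(x) {
  ifelse(grepl("[[:space:]]", x), paste0('"', x, '"'), x)
}

sig_quote_list <- function(xs) {
  paste(sig_quote(xs), collapse = ",")
}

tokenize_sigtext <- function(line) {
  # a token is a run of quoted segments and non-space characters, so
  # comma-separated lists with quoted members stay one token
  pat <- '(?:"[^"]*"|[^[:space:]"])+'
  toks <- regmatches(line, gregexpr(pat, line, perl = TRUE))[[1]]
  vapply(toks, function(t) gsub('"', "", t), "", USE.NAMES = FALSE)
}

split_ids <- function(field) {
  strsplit(field, ",", fixed = TRUE)[[1]]
}

#' Read a SIGTXT model file
#'
#' @param path Path to a SIGTXT file.
#' @return A compiled `boolean_system`.
#' @export
read_sigtext <- function(path) {
  lines <- readLines(path, warn = FALSE)
  events <- list()
  geninh <- list()
  signals <- list()
  for (ln in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[ln])
    if (!nzchar(trimws(raw))) next
    toks <- tokenize_sigtext(raw)
    err <- function(msg) {
      rlang::abort(sprintf("SIGTXT parse error at line %d: %s", ln, msg),
                   class = "boolsig_sigtext_error")
    }
    directive <- toupper(toks[1L])
    if (directive == "SIGNAL") {
      if (length(toks) < 2L) err("SIGNAL needs an id")
      rec <- list(id = toks[2L], name = toks[2L], xrefs = character())
      i <- 3L
      while (i <= length(toks)) {
        kw <- toupper(toks[i])
        if (kw == "NAME") {
          if (i + 1L > length(toks)) err("NAME needs a value")
          rec$name <- toks[i + 1L]; i <- i + 2L
        } else if (kw == "XREF") {
          if (i + 1L > length(toks)) err("XREF needs a value")
          rec$xrefs <- c(rec$xrefs, toks[i + 1L]); i <- i + 2L
        } else err(sprintf("unknown SIGNAL field '%s'", toks[i]))
      }
      signals[[length(signals) + 1L]] <- rec
    } else if (directive == "EVENT") {
      if (length(toks) < 2L) err("EVENT needs an id")
      rec <- list(id = toks[2L], inputs = character(), outputs = character(),
                  inhibitors = character(), catalysts = character())
      i <- 3L
      while (i <= length(toks)) {
        kw <- toupper(toks[i])
        field <- switch(kw, "IN" = "inputs", "OUT" = "outputs",
                        "INH" = "inhibitors", "CAT" = "catalysts", NULL)
        if (is.null(field)) err(sprintf("unknown EVENT field '%s'", toks[i]))
        if (i + 1L > length(toks)) err(sprintf("%s needs a value", kw))
        rec[[field]] <- split_ids(toks[i + 1L])
        i <- i + 2L
      }
      if (length(rec$outputs) == 0L) err("EVENT has no OUT field")
      events[[length(events) + 1L]] <- rec
    } else if (directive == "GENINH") {
      if (length(toks) != 4L || toupper(toks[3L]) != "OF") {
        err("GENINH syntax is: GENINH <inhibitor> OF <signal>")
      }
      geninh[[length(geninh) + 1L]] <-
        list(inhibitor = toks[2L], target = toks[4L])
    } else {
      err(sprintf("unknown directive '%s'", toks[1L]))
    }
  }
  ids <- vapply(events, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    rlang::abort(sprintf("duplicate event id(s): %s",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")),
                 class = "boolsig_duplicate_event")
  }
  ev_tbl <- purrr::map_dfr(events, function(e) {
    signalling_event(e$id, e$inputs, e$outputs, e$inhibitors, e$catalysts)
  })
  gi_tbl <- if (length(geninh)) purrr::map_dfr(geninh, tibble::as_tibble) else NULL
  sig_tbl <- if (length(signals)) {
    tibble::tibble(id = vapply(signals, `[[`, "", "id"),
                   name = vapply(signals, `[[`, "", "name"),
                   xrefs = lapply(signals, `[[`, "xrefs"))
  } else NULL
  boolean_system(ev_tbl, general_inhibitions = gi_tbl, signals = sig_tbl)
}

#' Write a system to SIGTXT
#'
#' Canonical, deterministic serialization: signals, events and general
#' inhibitions each sorted by id; a provenance comment heads the file.
#'
#' @param system A `boolean_system`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sigtext <- function(system, path) {
  stopifnot(inherits(system, "boolean_system"))
  sig_lines <- vapply(seq_len(nrow(system$signals)), function(i) {
    s <- system$signals[i, ]
    parts <- c("SIGNAL", sig_quote(s$id))
    if (!identical(s$name, s$id)) parts <- c(parts, "NAME", sig_quote(s$name))
    for (x in s$xrefs[[1]]) parts <- c(parts, "XREF", sig_quote(x))
    paste(parts, collapse = " ")
  }, "")
  ev <- system$events[order(system$events$id), ]
  ev_lines <- vapply(seq_len(nrow(ev)), function(i) {
    parts <- c("EVENT", sig_quote(ev$id[i]))
    if (length(ev$inputs[[i]])) parts <- c(parts, "IN", sig_quote_list(sort(ev$inputs[[i]])))
    parts <- c(parts, "OUT", sig_quote_list(sort(ev$outputs[[i]])))
    if (length(ev$inhibitors[[i]])) parts <- c(parts, "INH", sig_quote_list(sort(ev$inhibitors[[i]])))
    if (length(ev$catalysts[[i]])) parts <- c(parts, "CAT", sig_quote_list(sort(ev$catalysts[[i]])))
    paste(parts, collapse = " ")
  }, "")
  gi <- system$general_inhibitions
  gi_lines <- if (nrow(gi)) {
    sprintf("GENINH %s OF %s", sig_quote(gi$inhibitor), sig_quote(gi$target))
  } else character()
  body <- c(sig_lines, ev_lines, gi_lines)
  writeLines(c(provenance_line(body), body), path)
  invisible(path)
}
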