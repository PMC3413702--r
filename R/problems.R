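# The three query types over a compiled system, and the cut-based
# enumeration of minimal input sets with its pruning strategies.

as_state_fixing <- function(system, state, allow = c("any", "inputs")) {
  allow <- match.arg(allow)
  state <- unlist(state)
  if (length(state) == 0L) return(stats::setNames(integer(), character()))
  if (is.null(names(state)) || any(!nzchar(names(state)))) {
    rlang::abort("state fixings must be a named 0/1 vector",
                 class = "boolsig_invalid_fixing")
  }
  bad <- setdiff(names(state), system$signals$id)
  if (length(bad)) {
    rlang::abort(sprintf("state fixes unknown signal(s): %s",
                         paste(bad, collapse = ", ")),
                 class = "boolsig_unknown_id")
  }
  if (!all(state %in% c(0, 1))) {
    rlang::abort("state values must be 0 or 1", class = "boolsig_invalid_fixing")
  }
  stats::setNames(as.integer(state), names(state))
}

base_problem <- function(system) {
  clauses_to_ilp(to_cnf(system))
}

#' Minimum Input: fewest active system inputs consistent with a target state
#'
#' Fixes the requested signal states (outputs and/or internal nodes), sets
#' the objective to the sum over all system-input variables, and solves the
#' binary program. With `direction = "maximize"` the same problem maximizes
#' the number of active inputs instead.
#'
#' @param system A `boolean_system`.
#' @param target Named 0/1 vector of signal states to require.
#' @param direction `"minimize"` (default) or `"maximize"`.
#' @param cuts Character vector of input signals forced inactive (integer
#'   cuts; used by [minimal_input_sets()]).
#' @return A [solve_ilp()] `solve_result`; when optimal, the attribute-free
#'   field `active_inputs` lists the system inputs active in the witness.
#' @export
minimum_input <- function(system, target, direction = c("minimize", "maximize"),
                          cuts = character()) {
  stopifnot(inherits(system, "boolean_system"))
  direction <- match.arg(direction)
  target <- as_state_fixing(system, target)
  inputs <- classify_signals(system)$sources
  prob <- base_problem(system)
  prob <- set_objective(prob, stats::setNames(rep(1L, length(inputs)), inputs),
                        direction)
  prob <- fix_variables(prob, target)
  if (length(cuts)) {
    prob <- fix_variables(prob, stats::setNames(rep(0L, length(cuts)), cuts))
  }
  res <- solve_ilp(prob)
  if (res$status == "optimal") {
    res$active_inputs <- sort(inputs[res$assignment[inputs] == 1L])
  }
  res
}

#' Output Maximization: all outputs generable from given input states
#'
#' Fixes the supplied input states, fixes every unmentioned system input to
#' inactive unless `free_inputs = TRUE`, and maximizes the number of active
#' system outputs. When all inputs are fixed the output set is unique and
#' maximal.
#'
#' @param system A `boolean_system`.
#' @param input_states Named 0/1 vector over (a subset of) system inputs.
#' @param free_inputs If `TRUE`, inputs not mentioned are left free for the
#'   solver; if `FALSE` (default) they are fixed inactive.
#' @param strict If `TRUE` (default) fixing a non-input signal is an error;
#'   otherwise a warning.
#' @return A `solve_result`; when optimal, `active_outputs` lists the system
#'   outputs active in the witness.
#' @export
output_maximization <- function(system, input_states = integer(),
                                free_inputs = FALSE, strict = TRUE) {
  stopifnot(inherits(system, "boolean_system"))
  input_states <- as_state_fixing(system, input_states)
  cls <- classify_signals(system)
  noninput <- setdiff(names(input_states), cls$sources)
  if (length(noninput)) {
    msg <- sprintf("fixing non-input signal(s): %s",
                   paste(noninput, collapse = ", "))
    if (strict) rlang::abort(msg, class = "boolsig_invalid_fixing")
    rlang::warn(msg)
  }
  fixings <- input_states
  if (!free_inputs) {
    rest <- setdiff(cls$sources, names(input_states))
    fixings <- c(fixings, stats::setNames(rep(0L, length(rest)), rest))
  }
  prob <- base_problem(system)
  prob <- set_objective(prob,
                        stats::setNames(rep(1L, length(cls$sinks)), cls$sinks),
                        "maximize")
  prob <- fix_variables(prob, fixings)
  res <- solve_ilp(prob)
  if (res$status == "optimal") {
    res$active_outputs <- sort(cls$sinks[res$assignment[cls$sinks] == 1L])
  }
  res
}

#' Descendant count of the rejected powerset cut strategy
#'
#' A solution with `n` active inputs would spawn `2^n` descendant problems
#' under the naive powerset-of-cuts strategy; the implemented strategy spawns
#' only `n` single-variable cuts. Reported for cost accounting.
#'
#' @param n Number of active inputs in a solution (`n >= 0`).
#' @return `2^n`.
#' @export
powerset_descendant_count <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0, n == floor(n))
  2^n
}

#' Enumerate all distinct minimal input sets for a target state
#'
#' Solves the Minimum Input problem, then recursively spawns descendant
#' problems: a solution with `j` active inputs spawns `j` descendants, each
#' adding a single integer cut fixing one of those inputs inactive while
#' retaining all ancestor cuts, until every branch is infeasible. Identical
#' cut sets are solved once (memoized). Collected witnesses are
#' canonicalized, deduplicated, superset-filtered, and each survivor is
#' certified: feasibility (its members active, all other inputs inactive,
#' target holds) and minimality (with outside inputs inactive, requiring
#' strictly fewer active inputs is infeasible).
#'
#' If the target is achievable with zero active inputs the output is
#' constitutive and the (non-trivial) set collection is empty.
#'
#' @param system A `boolean_system`.
#' @param target Named 0/1 vector of required signal states.
#' @param max_solver_calls Budget of integer-program solves for this target;
#'   exceeding it raises a `boolsig_resource_error` carrying partial results
#'   in its `partial` field.
#' @return An object of class `minimal_input_sets`: fields `target`, `sets`
#'   (list of sorted character vectors), `constitutive`, `infeasible`,
#'   `solver_calls`.
#' @export
minimal_input_sets <- function(system, target, max_solver_calls = 1e6) {
  stopifnot(inherits(system, "boolean_system"))
  target <- as_state_fixing(system, target)
  inputs <- classify_signals(system)$sources
  prob0 <- base_problem(system)
  prob0 <- set_objective(prob0, stats::setNames(rep(1L, length(inputs)), inputs),
                         "minimize")
  prob0 <- fix_variables(prob0, target)

  calls <- 0L
  found <- list()
  budget_error <- function() {
    rlang::abort("minimal input set solver-call budget exceeded",
                 class = "boolsig_resource_error",
                 partial = mis_result(target, found, constitutive = FALSE,
                                      infeasible = FALSE, calls,
                                      complete = FALSE))
  }
  solve_node <- function(cuts) {
    if (calls + 1L > max_solver_calls) budget_error()
    calls <<- calls + 1L
    prob <- prob0
    if (length(cuts)) {
      prob <- fix_variables(prob, stats::setNames(rep(0L, length(cuts)), cuts))
    }
    solve_ilp(prob)
  }

  root <- solve_node(character())
  if (root$status == "infeasible") {
    return(mis_result(target, list(), constitutive = FALSE, infeasible = TRUE,
                      calls))
  }
  root_active <- sort(inputs[root$assignment[inputs] == 1L])
  if (length(root_active) == 0L) {
    return(mis_result(target, list(), constitutive = TRUE, infeasible = FALSE,
                      calls))
  }

  # depth-first over cut sets; a node is identified by its cut set, so
  # previously seen cut sets are never re-solved
  seen <- new.env(parent = emptyenv())
  cut_key <- function(cuts) paste0(".", paste(cuts, collapse = "\r"))
  stack <- list(list(cuts = character(), res = root, active = root_active))
  assign(cut_key(character()), TRUE, envir = seen)
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    found[[length(found) + 1L]] <- node$active
    for (w in node$active) {
      cuts <- sort(c(node$cuts, w))
      key <- cut_key(cuts)
      if (!is.null(seen[[key]])) next
      assign(key, TRUE, envir = seen)
      res <- solve_node(cuts)
      if (res$status == "infeasible") next
      active <- sort(inputs[res$assignment[inputs] == 1L])
      if (length(active) == 0L) next  # trivial (empty) combination
      stack[[length(stack) + 1L]] <- list(cuts = cuts, res = res, active = active)
    }
  }

  # canonicalize: dedupe, drop supersets, then certify each survivor
  keys <- vapply(found, paste, "", collapse = "\r")
  found <- found[!duplicated(keys)]
  if (length(found) > 1L) {
    is_superset <- vapply(seq_along(found), function(i) {
      any(vapply(seq_along(found), function(j) {
        i != j && length(found[[j]]) < length(found[[i]]) &&
          all(found[[j]] %in% found[[i]])
      }, TRUE))
    }, TRUE)
    found <- found[!is_superset]
  }
  certify <- function(set) {
    if (calls + 2L > max_solver_calls) budget_error()
    outside <- setdiff(inputs, set)
    fx <- c(stats::setNames(rep(1L, length(set)), set),
            stats::setNames(rep(0L, length(outside)), outside))
    calls <<- calls + 1L
    feas <- solve_ilp(fix_variables(prob0, fx))
    if (feas$status != "optimal") return(FALSE)
    # minimality: outside inputs inactive, strictly fewer actives required
    prob <- fix_variables(prob0, stats::setNames(rep(0L, length(outside)), outside))
    prob <- add_constraint(prob,
                           stats::setNames(rep(1L, length(inputs)), inputs),
                           "<=", length(set) - 1L)
    calls <<- calls + 1L
    smaller <- solve_ilp(prob)
    smaller$status == "infeasible"
  }
  ok <- vapply(found, certify, TRUE)
  found <- found[ok]
  ord <- order(lengths(found), vapply(found, paste, "", collapse = "\r"))
  mis_result(target, found[ord], constitutive = FALSE, infeasible = FALSE, calls)
}

mis_result <- function(target, sets, constitutive, infeasible, solver_calls,
                       complete = TRUE) {
  structure(list(target = target, sets = sets, constitutive = constitutive,
                 infeasible = infeasible, solver_calls = solver_calls,
                 complete = complete),
            class = "minimal_input_sets")
}

#' @export
print.minimal_input_sets <- function(x, ...) {
  cat(sprintf("<minimal_input_sets> target {%s}: ",
              paste(sprintf("%s=%d", names(x$target), x$target), collapse = ", ")))
  if (x$infeasible) {
    cat("infeasible\n")
  } else if (x$constitutive) {
    cat("constitutive output (empty minimal input set)\n")
  } else {
    cat(sprintf("%d set(s), %d solver call(s)\n", length(x$sets), x$solver_calls))
    for (s in x$sets) cat("  {", paste(s, collapse = ", "), "}\n")
  }
  invisible(x)
}

#' Tidy minimal input sets: one row per (set, signal)
#' @param x A `minimal_input_sets`.
#' @param ... Unused.
#' @return Tibble with columns `set`, `size`, `signal`.
#' @export
tidy.minimal_input_sets <- function(x, ...) {
  if (length(x$sets) == 0L) {
    return(tibble::tibble(set = integer(), size = integer(), signal = character()))
  }
  purrr::imap_dfr(x$sets, function(s, i) {
    tibble::tibble(set = i, size = length(s), signal = s)
  })
}

#' One-row summary of a minimal-input-set result
#' @param x A `minimal_input_sets`.
#' @param ... Unused.
#' @return Tibble with set count, size range, flags and solver calls.
#' @export
glance.minimal_input_sets <- function(x, ...) {
  tibble::tibble(
    n_sets = length(x$sets),
    min_size = if (length(x$sets)) min(lengths(x$sets)) else NA_integer_,
    median_size = if (length(x$sets)) stats::median(lengths(x$sets)) else NA_real_,
    constitutive = x$constitutive, infeasible = x$infeasible,
    solver_calls = x$solver_calls, complete = x$complete)
}

# ---- independent oracle ----------------------------------------------------

# Evaluate the statement system directly as Boolean equivalences under a
# complete named 0/1 assignment (no CNF, no integer program).
eval_statements <- function(system, assignment) {
  for (st in statements(system)) {
    lhs <- if (st$kind == "event-activation") {
      all(assignment[st$pos] == 1L) && !any(assignment[st$neg] == 1L)
    } else {
      any(assignment[st$pos] == 1L)
    }
    if (as.integer(lhs) != assignment[[st$consequent]]) return(FALSE)
  }
  TRUE
}

# Precomputed evaluation context for the oracle: topological statement
# order (when acyclic), free-variable set, statement lookup.
oracle_context <- function(system) {
  cls <- classify_signals(system)
  vars <- variables(system)
  g <- dependency_graph(system)
  acyclic <- igraph::is_dag(g)
  st_by_var <- statements(system)
  names(st_by_var) <- vapply(st_by_var, `[[`, "", "consequent")
  free <- setdiff(vars, c(cls$sources, cls$isolated))
  eval_order <- if (acyclic) {
    intersect(igraph::V(g)$name[igraph::topo_sort(g, mode = "out")], free)
  } else NULL
  list(inputs = cls$sources, vars = vars, free = free, acyclic = acyclic,
       eval_order = eval_order, st_by_var = st_by_var)
}

# Can the target state be achieved with exactly `active` inputs on, all
# other system inputs off? Acyclic systems are evaluated by propagation in
# topological order (the equivalences then have a unique solution given the
# inputs); cyclic systems fall back to exhaustive search over the non-input
# variables.
target_achievable <- function(system, active, target, max_free = 20L,
                              ctx = oracle_context(system)) {
  asg <- stats::setNames(integer(length(ctx$vars)), ctx$vars)
  asg[ctx$inputs] <- 0L
  asg[active] <- 1L
  if (ctx$acyclic) {
    for (v in ctx$eval_order) {
      st <- ctx$st_by_var[[v]]
      asg[[v]] <- if (st$kind == "event-activation") {
        as.integer(all(asg[st$pos] == 1L) && !any(asg[st$neg] == 1L))
      } else {
        as.integer(any(asg[st$pos] == 1L))
      }
    }
    return(all(asg[names(target)] == target))
  }
  free <- ctx$free
  if (length(free) > max_free) {
    rlang::abort(sprintf("cyclic system with %d free variables exceeds oracle cap",
                         length(free)),
                 class = "boolsig_resource_error")
  }
  for (code in seq_len(2^length(free)) - 1L) {
    asg[free] <- bit_pattern(code, length(free))
    if (all(asg[names(target)] == target) && eval_statements(system, asg)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Brute-force enumeration of minimal input sets (correctness oracle)
#'
#' Enumerates every combination of system inputs, tests whether the target
#' state is achievable with exactly that combination active (by direct
#' evaluation of the Boolean statements, independent of the integer-program
#' path), and reduces the achieving combinations to the distinct minimal
#' sets. Intended as the oracle for [minimal_input_sets()] on small systems.
#'
#' @param system A `boolean_system`.
#' @param target Named 0/1 vector of required signal states.
#' @param max_inputs Cap on the number of system inputs (default 16).
#' @param max_vars Cap on the total variable count (default 24).
#' @return A `minimal_input_sets` object.
#' @export
brute_force_minimal_input_sets <- function(system, target,
                                           max_inputs = 16L, max_vars = 24L) {
  stopifnot(inherits(system, "boolean_system"))
  target <- as_state_fixing(system, target)
  inputs <- classify_signals(system)$sources
  if (length(inputs) > max_inputs) {
    rlang::abort(sprintf("%d system inputs exceeds brute-force cap of %d",
                         length(inputs), max_inputs),
                 class = "boolsig_resource_error")
  }
  if (length(variables(system)) > max_vars) {
    rlang::abort(sprintf("%d variables exceeds brute-force cap of %d",
                         length(variables(system)), max_vars),
                 class = "boolsig_resource_error")
  }
  n <- length(inputs)
  ctx <- oracle_context(system)
  achieving <- list()
  for (code in seq_len(2^n) - 1L) {
    active <- inputs[bit_pattern(code, n) == 1L]
    if (target_achievable(system, active, target, ctx = ctx)) {
      achieving[[length(achieving) + 1L]] <- sort(active)
    }
  }
  if (length(achieving) == 0L) {
    return(mis_result(target, list(), constitutive = FALSE, infeasible = TRUE, 0L))
  }
  if (any(lengths(achieving) == 0L)) {
    return(mis_result(target, list(), constitutive = TRUE, infeasible = FALSE, 0L))
  }
  minimal <- achieving[vapply(seq_along(achieving), function(i) {
    !any(vapply(seq_along(achieving), function(j) {
      j != i && length(achieving[[j]]) < length(achieving[[i]]) &&
        all(achieving[[j]] %in% achieving[[i]])
    }, TRUE))
  }, TRUE)]
  keys <- vapply(minimal, paste, "", collapse = "\r")
  minimal <- minimal[!duplicated(keys)]
  ord <- order(lengths(minimal), vapply(minimal, paste, "", collapse = "\r"))
  mis_result(target, minimal[ord], constitutive = FALSE, infeasible = FALSE, 0L)
}

# ---- dataset-level summaries ----------------------------------------------

#' Group system outputs whose producing-reaction sets are identical
#'
#' Redundant outputs (identical incident edges) get identical analysis
#' results, so batch queries compute once per group and copy the result.
#'
#' @param system A `boolean_system`.
#' @return A list of character vectors partitioning the system outputs;
#'   groups and members are sorted.
#' @export
redundant_output_groups <- function(system) {
  stopifnot(inherits(system, "boolean_system"))
  sinks <- classify_signals(system)$sinks
  if (length(sinks) == 0L) return(list())
  key <- vapply(sinks, function(s) {
    prods <- system$events$id[purrr::map_lgl(system$events$outputs, ~ s %in% .x)]
    paste(sort(prods), collapse = "\r")
  }, "")
  groups <- split(sinks, key)
  groups <- lapply(groups, sort)
  names(groups) <- NULL
  groups[order(vapply(groups, `[`, "", 1L))]
}

#' Per-output Minimum Input and Minimal Input Set summary
#'
#' For every system output: the Minimum Input objective with that output
#' fixed active, and the number of distinct minimal input sets. Redundant
#' outputs are computed once per group. Aggregate statistics report both
#' averaging conventions (over all outputs, and over feasible
#' non-constitutive outputs only).
#'
#' @param system A `boolean_system`.
#' @param group_redundant Use [redundant_output_groups()] to avoid duplicate
#'   computation (default `TRUE`).
#' @param max_solver_calls Per-output solver budget; a budget overrun is
#'   recorded in that output's row, not propagated.
#' @return An object of class `output_summary`; `tidy()` returns the
#'   per-output rows, `glance()` the aggregates.
#' @export
summarize_outputs <- function(system, group_redundant = TRUE,
                              max_solver_calls = 1e6) {
  stopifnot(inherits(system, "boolean_system"))
  groups <- if (group_redundant) redundant_output_groups(system) else {
    as.list(classify_signals(system)$sinks)
  }
  rows <- purrr::map_dfr(groups, function(members) {
    rep_out <- members[[1L]]
    target <- stats::setNames(1L, rep_out)
    mi <- minimum_input(system, target)
    if (mi$status == "infeasible") {
      row <- tibble::tibble(output = rep_out, min_input = NA_integer_,
                            mis_size = NA_integer_, constitutive = FALSE,
                            infeasible = TRUE, complete = TRUE)
    } else {
      mis <- tryCatch(
        minimal_input_sets(system, target, max_solver_calls = max_solver_calls),
        boolsig_resource_error = function(e) e$partial)
      row <- tibble::tibble(output = rep_out,
                            min_input = as.integer(mi$objective_value),
                            mis_size = length(mis$sets),
                            constitutive = mis$constitutive,
                            infeasible = FALSE, complete = mis$complete)
    }
    row[rep(1L, length(members)), ] |>
      dplyr::mutate(output = members, copied = members != rep_out)
  })
  rows <- dplyr::arrange(rows, .data$output)
  rows$name <- system$signals$name[match(rows$output, system$signals$id)]
  rows <- dplyr::relocate(rows, "output", "name")
  feas <- dplyr::filter(rows, !.data$infeasible, !.data$constitutive)
  agg <- tibble::tibble(
    n_outputs = nrow(rows),
    mean_min_input = mean(feas$min_input),
    median_min_input = stats::median(feas$min_input),
    mean_min_input_all = mean(rows$min_input),
    median_mis_size = stats::median(feas$mis_size),
    pct_mis_gt1 = if (nrow(feas)) 100 * mean(feas$mis_size > 1) else NA_real_)
  structure(list(outputs = rows, aggregates = agg), class = "output_summary")
}

#' @export
print.output_summary <- function(x, ...) {
  cat(sprintf("<output_summary> %d outputs\n", nrow(x$outputs)))
  print(x$outputs)
  print(x$aggregates)
  invisible(x)
}

#' @rdname summarize_outputs
#' @param x An `output_summary`.
#' @param ... Unused.
#' @export
tidy.output_summary <- function(x, ...) x$outputs

#' @rdname summarize_outputs
#' @export
glance.output_summary <- function(x, ...) x$aggregates

#' Write an output summary as tab-delimited text
#'
#' One row per output plus an aggregate footer; a provenance comment heads
#' the file.
#'
#' @param summary An `output_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(summary, path) {
  stopifnot(inherits(summary, "output_summary"))
  rows <- summary$outputs
  header <- paste(c("output", "name", "min_input", "mis_size", "constitutive",
                    "infeasible"), collapse = "\t")
  body <- vapply(seq_len(nrow(rows)), function(i) {
    paste(c(rows$output[i], rows$name[i],
            ifelse(is.na(rows$min_input[i]), "-", rows$min_input[i]),
            ifelse(is.na(rows$mis_size[i]), "-", rows$mis_size[i]),
            as.integer(rows$constitutive[i]), as.integer(rows$infeasible[i])),
          collapse = "\t")
  }, "")
  agg <- summary$aggregates
  footer <- c(
    sprintf("# mean_min_input\t%s", format(agg$mean_min_input)),
    sprintf("# median_min_input\t%s", format(agg$median_min_input)),
    sprintf("# median_mis_size\t%s", format(agg$median_mis_size)),
    sprintf("# pct_mis_gt1\t%s", format(agg$pct_mis_gt1)))
  writeLines(c(provenance_line(rows), header, body, footer), path)
  invisible(path)
}

provenance_line <- function(x, seed = NA) {
  sprintf("# boolsig %s hash:%s seed:%s",
          as.character(utils::packageVersion("boolsig")),
          rlang::hash(x), as.character(seed))
}
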