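# Narrow adapter around the exact 0/1 branch-and-bound back end. Every
# optimization in the package funnels through solve_ilp() so that solver
# calls can be counted (the enumeration algorithms report and bound them).

.boolsig_env <- new.env(parent = emptyenv())
.boolsig_env$solver_calls <- 0L

#' Number of integer-program solves since the last reset
#' @return Integer count.
#' @export
solver_calls <- function() .boolsig_env$solver_calls

#' Reset the solver-call counter
#' @return The previous count, invisibly.
#' @export
reset_solver_calls <- function() {
  old <- .boolsig_env$solver_calls
  .boolsig_env$solver_calls <- 0L
  invisible(old)
}

#' Solve a binary integer program exactly
#'
#' Depth-first branch and bound with constraint propagation; all variables
#' are binary, all data integer. The optimal objective value is unique and
#' deterministic; the witness assignment is one optimal assignment (ties are
#' broken by a fixed branching order, and no downstream algorithm depends on
#' which co-optimal witness is returned).
#'
#' @param problem An `ilp_problem`.
#' @param node_limit Search-node budget; exceeding it raises a
#'   `boolsig_solver_limit` error (never silently reported as infeasible).
#' @return An object of class `solve_result`: list with `status`
#'   (`"optimal"` or `"infeasible"`), and when optimal `assignment` (named
#'   0/1 integer vector over all variables) and `objective_value`.
#' @export
solve_ilp <- function(problem, node_limit = getOption("boolsig.node_limit", 1e7)) {
  stopifnot(inherits(problem, "ilp_problem"))
  vars <- problem$variables
  n <- length(vars)
  idx <- stats::setNames(seq_len(n) - 1L, vars)
  cons_idx <- lapply(problem$constraints, function(cn) unname(idx[names(cn$coefficients)]))
  cons_coef <- lapply(problem$constraints, function(cn) as.integer(cn$coefficients))
  sense_code <- c(">=" = 0L, "<=" = 1L, "=" = 2L)
  cons_sense <- vapply(problem$constraints, function(cn) sense_code[[cn$sense]], 0L)
  cons_rhs <- vapply(problem$constraints, function(cn) as.numeric(cn$rhs), 0)
  obj <- numeric(n)
  maximize <- identical(problem$direction, "maximize")
  if (!is.null(problem$objective)) {
    obj[idx[names(problem$objective)] + 1L] <- as.numeric(problem$objective)
    if (maximize) obj <- -obj
  }
  fix <- rep(-1L, n)
  if (length(problem$fixings)) {
    fix[idx[names(problem$fixings)] + 1L] <- as.integer(problem$fixings)
  }
  .boolsig_env$solver_calls <- .boolsig_env$solver_calls + 1L
  res <- .bip_solve_cpp(n, cons_idx, cons_coef, as.integer(cons_sense),
                        cons_rhs, obj, fix, as.numeric(node_limit))
  if (identical(res$status, "limit")) {
    rlang::abort(sprintf("solver node limit (%g) exceeded", node_limit),
                 class = "boolsig_solver_limit")
  }
  if (identical(res$status, "infeasible")) {
    return(structure(list(status = "infeasible"), class = "solve_result"))
  }
  assignment <- stats::setNames(as.integer(res$assignment), vars)
  objective_value <- if (is.null(problem$objective)) NA_real_
                     else (if (maximize) -res$objective else res$objective)
  structure(list(status = "optimal", assignment = assignment,
                 objective_value = objective_value),
            class = "solve_result")
}

#' @export
print.solve_result <- function(x, ...) {
  if (x$status == "infeasible") {
    cat("<solve_result> infeasible\n")
  } else {
    cat(sprintf("<solve_result> optimal, objective %s, %d active variables\n",
                format(x$objective_value), sum(x$assignment == 1L)))
  }
  invisible(x)
}

#' Tidy a solver result: one row per variable
#' @param x A `solve_result`.
#' @param ... Unused.
#' @return Tibble with columns `variable`, `value` (empty when infeasible).
#' @export
tidy.solve_result <- function(x, ...) {
  if (x$status == "infeasible") {
    return(tibble::tibble(variable = character(), value = integer()))
  }
  tibble::tibble(variable = names(x$assignment), value = unname(x$assignment))
}

#' One-row summary of a solver result
#' @param x A `solve_result`.
#' @param ... Unused.
#' @return Tibble with `status`, `objective_value`, `n_active`.
#' @export
glance.solve_result <- function(x, ...) {
  tibble::tibble(
    status = x$status,
    objective_value = if (x$status == "optimal") x$objective_value else NA_real_,
    n_active = if (x$status == "optimal") sum(x$assignment == 1L) else NA_integer_)
}
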