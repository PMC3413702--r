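#' Rewrite a Boolean system in conjunctive normal form
#'
#' Each statement is encoded as a logical equivalence. For an activation
#' statement `r <=> (x1 & ... & xk & !z1 & ... & !zq)` the clauses are
#' `(!r | xi)` for every input, `(!r | !zj)` for every inhibitor, and
#' `(r | !x1 | ... | !xk | z1 | ... | zq)`. For a derivation statement
#' `s <=> (r1 | ... | rp)` the clauses are `(!s | r1 | ... | rp)` and
#' `(s | !ri)` for each producer. An event with no inputs and no inhibitors
#' yields the unit clause `(r)` (equivalence with the empty conjunction).
#'
#' Encoding both directions is what gives the documented inhibition
#' behaviour: the absence of an inhibitor is not by itself sufficient to
#' activate the inhibited signal, and a fixed-active output forces some
#' producing reaction (and hence some inputs) to be active.
#'
#' @param system A `boolean_system`.
#' @return An object of class `cnf`: a list of clauses, each a list with
#'   character vectors `pos` and `neg`, in canonical (statement-sorted) order.
#' @export
to_cnf <- function(system) {
  stopifnot(inherits(system, "boolean_system"))
  sts <- statements(system)
  ord <- order(vapply(sts, `[[`, "", "consequent"))
  clauses <- list()
  for (st in sts[ord]) {
    v <- st$consequent
    if (st$kind == "event-activation") {
      for (x in st$pos) clauses[[length(clauses) + 1L]] <-
          list(pos = x, neg = v)
      for (z in st$neg) clauses[[length(clauses) + 1L]] <-
          list(pos = character(), neg = sort(c(v, z)))
      clauses[[length(clauses) + 1L]] <-
        list(pos = sort(c(v, st$neg)), neg = st$pos)
    } else {
      clauses[[length(clauses) + 1L]] <-
        list(pos = sort(st$pos), neg = v)
      for (r in st$pos) clauses[[length(clauses) + 1L]] <-
          list(pos = v, neg = r)
    }
  }
  structure(clauses, class = "cnf", variables = variables(system))
}

#' Check an assignment against a clause set
#'
#' @param clauses A `cnf` object or plain list of clauses (`pos`/`neg`).
#' @param assignment Named integer/logical vector covering every variable
#'   appearing in the clauses.
#' @return `TRUE` iff every clause contains at least one satisfied literal.
#' @export
satisfies <- function(clauses, assignment) {
  vals <- as.integer(assignment)
  names(vals) <- names(assignment)
  used <- unique(unlist(lapply(clauses, function(cl) c(cl$pos, cl$neg))))
  miss <- setdiff(used, names(vals))
  if (length(miss)) {
    rlang::abort(sprintf("assignment missing variable(s): %s",
                         paste(miss, collapse = ", ")),
                 class = "boolsig_missing_variable")
  }
  for (cl in clauses) {
    if (any(vals[cl$pos] == 1L) || any(vals[cl$neg] == 0L)) next
    return(FALSE)
  }
  TRUE
}

#' Count satisfying assignments of a clause set by exhaustive enumeration
#'
#' Intended for small systems (the free-variable count is capped); used to
#' verify, e.g., that the uncurated complex-dissociation loop admits exactly
#' two satisfying assignments once its output is fixed active.
#'
#' @param clauses A `cnf` object (or list of clauses).
#' @param variables Character vector of all variables; defaults to the
#'   `variables` attribute of `clauses`.
#' @param fixings Named 0/1 vector of fixed variables.
#' @param max_free Maximum number of free variables to enumerate over.
#' @return Integer count of satisfying assignments.
#' @export
count_satisfying <- function(clauses, variables = attr(clauses, "variables"),
                             fixings = integer(), max_free = 20L) {
  stopifnot(!is.null(variables))
  free <- setdiff(variables, names(fixings))
  if (length(free) > max_free) {
    rlang::abort(sprintf("%d free variables exceeds cap of %d",
                         length(free), max_free),
                 class = "boolsig_resource_error")
  }
  n <- length(free)
  count <- 0L
  asg <- c(as.integer(fixings), integer(length(free)))
  names(asg) <- c(names(fixings), free)
  for (code in seq_len(2^n) - 1L) {
    if (n > 0L) asg[free] <- bit_pattern(code, n)
    if (satisfies(clauses, asg)) count <- count + 1L
  }
  count
}

bit_pattern <- function(code, n) {
  as.integer(bitwAnd(bitwShiftR(code, seq_len(n) - 1L), 1L))
}

#' Translate CNF clauses to a binary integer program
#'
#' One linear constraint per clause: the sum of positive-literal variables
#' plus the sum of `(1 - v)` over negative-literal variables must be at least
#' one, i.e. `sum(pos) - sum(neg) >= 1 - |neg|`. All variables are binary; no
#' objective is set.
#'
#' @param clauses A `cnf` object or list of clauses.
#' @param variables Character vector of all variables (defaults to the
#'   `variables` attribute, else the union over clauses).
#' @return An object of class `ilp_problem` with fields `variables`,
#'   `constraints` (each `coefficients` named integer vector, `sense`
#'   in `">=" "<=" "="`, `rhs`), `objective`, `direction`, `fixings`.
#' @export
clauses_to_ilp <- function(clauses, variables = attr(clauses, "variables")) {
  if (is.null(variables)) {
    variables <- sort(unique(unlist(lapply(clauses, function(cl) c(cl$pos, cl$neg)))))
  }
  constraints <- lapply(clauses, function(cl) {
    coef <- c(rep(1L, length(cl$pos)), rep(-1L, length(cl$neg)))
    names(coef) <- c(cl$pos, cl$neg)
    list(coefficients = coef, sense = ">=", rhs = 1L - length(cl$neg))
  })
  new_ilp_problem(variables, constraints)
}

new_ilp_problem <- function(variables, constraints = list(),
                            objective = NULL, direction = "minimize",
                            fixings = integer()) {
  structure(list(variables = variables, constraints = constraints,
                 objective = objective, direction = direction,
                 fixings = fixings),
            class = "ilp_problem")
}

#' Set the objective of a binary program
#' @param problem An `ilp_problem`.
#' @param objective Named numeric vector of coefficients over a subset of the
#'   problem variables.
#' @param direction `"minimize"` or `"maximize"`.
#' @return The updated problem.
#' @export
set_objective <- function(problem, objective,
                          direction = c("minimize", "maximize")) {
  stopifnot(inherits(problem, "ilp_problem"))
  direction <- match.arg(direction)
  bad <- setdiff(names(objective), problem$variables)
  if (length(bad)) {
    rlang::abort(sprintf("objective over unknown variable(s): %s",
                         paste(bad, collapse = ", ")),
                 class = "boolsig_unknown_id")
  }
  problem$objective <- objective
  problem$direction <- direction
  problem
}

#' Fix variables of a binary program to 0/1 values
#' @param problem An `ilp_problem`.
#' @param fixings Named 0/1 vector.
#' @return The updated problem (later fixings overwrite earlier ones for the
#'   same variable).
#' @export
fix_variables <- function(problem, fixings) {
  stopifnot(inherits(problem, "ilp_problem"))
  if (length(fixings) == 0L) return(problem)
  bad <- setdiff(names(fixings), problem$variables)
  if (length(bad)) {
    rlang::abort(sprintf("fixing unknown variable(s): %s",
                         paste(bad, collapse = ", ")),
                 class = "boolsig_unknown_id")
  }
  stopifnot(all(fixings %in% c(0, 1)))
  merged <- problem$fixings
  merged[names(fixings)] <- as.integer(fixings)
  problem$fixings <- merged
  problem
}

add_constraint <- function(problem, coefficients, sense, rhs) {
  problem$constraints[[length(problem$constraints) + 1L]] <-
    list(coefficients = coefficients, sense = sense, rhs = rhs)
  problem
}

#' Export a binary program in LP file format (debugging aid)
#' @param problem An `ilp_problem`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lp <- function(problem, path) {
  stopifnot(inherits(problem, "ilp_problem"))
  term <- function(coef) {
    paste(sprintf("%+d %s", as.integer(coef), lp_name(names(coef))),
          collapse = " ")
  }
  obj <- problem$objective
  if (is.null(obj)) obj <- stats::setNames(0L, problem$variables[1])
  lines <- c(
    if (problem$direction == "maximize") "Maximize" else "Minimize",
    paste(" obj:", term(obj)),
    "Subject To",
    vapply(seq_along(problem$constraints), function(i) {
      cn <- problem$constraints[[i]]
      sense <- c(">=" = ">=", "<=" = "<=", "=" = "=")[[cn$sense]]
      sprintf(" c%d: %s %s %d", i, term(cn$coefficients), sense,
              as.integer(cn$rhs))
    }, ""),
    if (length(problem$fixings)) c(
      "Bounds",
      sprintf(" %s = %d", lp_name(names(problem$fixings)),
              as.integer(problem$fixings))
    ),
    "Binary",
    paste("", paste(lp_name(problem$variables), collapse = " ")),
    "End")
  writeLines(lines, path)
  invisible(path)
}

# LP format forbids several characters common in biological ids (":", "'")
lp_name <- function(x) gsub("[^A-Za-z0-9_.]", "_", x)
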