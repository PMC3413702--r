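# Minimum Input, Output Maximization, Minimal Input Sets and summaries.

test_that("minimum_input reproduces the loop and inhibition worked examples", {
  mi <- minimum_input(toy_loop_model(), c("J'" = 1))
  expect_equal(mi$objective_value, 1)
  expect_equal(mi$active_inputs, "J")

  mi2 <- minimum_input(toy_loop_model(curated = TRUE), c("J'" = 1))
  expect_equal(mi2$objective_value, 2)
  expect_equal(mi2$active_inputs, c("I", "J"))

  mi3 <- minimum_input(toy_inhibition_model(), c(S2 = 1))
  expect_equal(mi3$objective_value, 1)
  expect_equal(mi3$assignment[["I"]], 0L)
  expect_equal(mi3$assignment[["S1"]], 1L)

  expect_error(minimum_input(toy_inhibition_model(), c(nope = 1)),
               class = "boolsig_unknown_id")
})

test_that("output_maximization reproduces the event-level inhibition behaviour", {
  sys <- toy_inhibition_model()
  r1 <- output_maximization(sys, c(S1 = 1, I = 0))
  expect_equal(r1$status, "optimal")
  expect_equal(r1$assignment[["S2"]], 1L)

  r2 <- output_maximization(sys, c(S1 = 0, I = 0))
  expect_equal(r2$assignment[["S2"]], 0L)

  r3 <- output_maximization(sys, c(S1 = 1, I = 1))
  expect_equal(r3$status, "optimal")  # co-occurrence stays feasible
  expect_equal(r3$assignment[["S2"]], 0L)

  expect_error(output_maximization(chain_system(), c(B = 1)),
               class = "boolsig_invalid_fixing")
  expect_warning(output_maximization(chain_system(), c(B = 1), strict = FALSE))
})

test_that("with all inputs inactive and no constitutive events, every output is off", {
  for (seed in c(3L, 8L, 21L)) {
    sys <- random_fixture(seed)
    cls <- classify_signals(sys)
    fix0 <- stats::setNames(rep(0L, length(cls$sources)), cls$sources)
    r <- output_maximization(sys, fix0)
    expect_equal(r$status, "optimal")
    expect_equal(unname(r$assignment[cls$sinks]),
                 rep(0L, length(cls$sinks)))
  }
})

test_that("unfixed inputs stay inactive unless freed", {
  sys <- diamond_system()
  r <- output_maximization(sys, c(A = 0))
  expect_equal(r$assignment[["O"]], 0L)
  rf <- output_maximization(sys, c(A = 0), free_inputs = TRUE)
  expect_equal(rf$assignment[["O"]], 1L)  # solver may turn B on
})

test_that("powerset_descendant_count follows 2^n", {
  expect_equal(powerset_descendant_count(10), 1024)
  expect_equal(powerset_descendant_count(0), 1)
  expect_equal(powerset_descendant_count(5), 32)
})

test_that("minimal_input_sets handles constitutive, diamond and infeasible targets", {
  con <- boolean_system(dplyr::bind_rows(
    signalling_event("e0", character(), "O"),
    signalling_event("e1", "A", "O")))
  m <- minimal_input_sets(con, c(O = 1))
  expect_true(m$constitutive)
  expect_length(m$sets, 0L)

  dia <- minimal_input_sets(diamond_system(), c(O = 1))
  expect_equal(dia$sets, list("A", "B"))

  # output fixed active and its only producer's inhibitor active: infeasible
  inh <- boolean_system(signalling_event("e1", "S1", "S2", inhibitors = "I"))
  mi <- minimal_input_sets(inh, c(S2 = 1, I = 1))
  expect_true(mi$infeasible)
  expect_length(mi$sets, 0L)
})

test_that("solver-call budget overrun raises a resource error carrying partial results", {
  err <- tryCatch(
    minimal_input_sets(diamond_system(), c(O = 1), max_solver_calls = 2),
    boolsig_resource_error = function(e) e)
  expect_s3_class(err, "boolsig_resource_error")
  expect_s3_class(err$partial, "minimal_input_sets")
  expect_false(err$partial$complete)
})

test_that("cut enumeration equals the brute-force oracle on random systems", {
  # a slice of the acceptance sweep; the full 100-seed run lives in the
  # acceptance suite
  for (seed in 0:14) {
    sys <- random_fixture(seed)
    sinks <- classify_signals(sys)$sinks
    for (s in sinks[seq_len(min(2L, length(sinks)))]) {
      target <- stats::setNames(1L, s)
      a <- minimal_input_sets(sys, target)
      b <- brute_force_minimal_input_sets(sys, target, max_vars = 40L)
      expect_identical(a$sets, b$sets)
      expect_equal(a$constitutive, b$constitutive)
      expect_equal(a$infeasible, b$infeasible)
      expect_mis_invariants(a, sys, target)
    }
  }
})

test_that("brute-force oracle reproduces the worked loop result and respects caps", {
  bf <- brute_force_minimal_input_sets(toy_loop_model(), c("J'" = 1))
  expect_equal(bf$sets, list("J"))
  bf2 <- brute_force_minimal_input_sets(toy_loop_model(curated = TRUE), c("J'" = 1))
  expect_equal(bf2$sets, list(c("I", "J")))
  expect_error(
    brute_force_minimal_input_sets(diamond_system(), c(O = 1), max_inputs = 1L),
    class = "boolsig_resource_error")
})

test_that("removing an event never decreases a minimum-input objective", {
  for (seed in c(6L, 13L)) {
    sys <- random_fixture(seed)
    sinks <- classify_signals(sys)$sinks
    s <- sinks[1]
    base <- minimum_input(sys, stats::setNames(1L, s))
    base_obj <- if (base$status == "optimal") base$objective_value else Inf
    for (drop_ev in sys$events$id[seq_len(min(4L, nrow(sys$events)))]) {
      ev2 <- sys$events[sys$events$id != drop_ev, , drop = FALSE]
      if (!s %in% unlist(ev2$outputs)) next  # target no longer produced
      sys2 <- boolean_system(ev2)
      if (!s %in% classify_signals(sys2)$sinks) next
      r2 <- minimum_input(sys2, stats::setNames(1L, s))
      obj2 <- if (r2$status == "optimal") r2$objective_value else Inf
      expect_gte(obj2, base_obj)
    }
  }
})

test_that("redundant outputs are grouped by identical producer sets", {
  dup <- boolean_system(dplyr::bind_rows(
    signalling_event("e1", "A", c("O1", "O2")),
    signalling_event("e2", "B", c("O1", "O2"))))
  expect_equal(redundant_output_groups(dup), list(c("O1", "O2")))
  expect_equal(redundant_output_groups(diamond_system()), list("O"))
  two <- boolean_system(dplyr::bind_rows(
    signalling_event("e1", "A", "O1"),
    signalling_event("e2", "B", "O2")))
  expect_equal(redundant_output_groups(two), list("O1", "O2"))
})

test_that("redundancy grouping strictly reduces solver calls on duplicated outputs", {
  dup <- boolean_system(dplyr::bind_rows(
    signalling_event("e1", "A", c("O1", "O2")),
    signalling_event("e2", "B", c("O1", "O2"))))
  reset_solver_calls()
  grouped <- summarize_outputs(dup, group_redundant = TRUE)
  calls_grouped <- solver_calls()
  reset_solver_calls()
  ungrouped <- summarize_outputs(dup, group_redundant = FALSE)
  calls_ungrouped <- solver_calls()
  expect_lt(calls_grouped, calls_ungrouped)
  expect_equal(dplyr::select(tidy(grouped), -"copied"),
               dplyr::select(tidy(ungrouped), -"copied"))
})

test_that("summarize_outputs reports per-output rows and recomputable aggregates", {
  smry <- summarize_outputs(diamond_system())
  rows <- tidy(smry)
  expect_equal(rows$min_input, 1L)
  expect_equal(rows$mis_size, 2L)
  agg <- glance(smry)
  expect_equal(agg$mean_min_input, 1)
  expect_equal(agg$median_mis_size, 2)
  expect_equal(agg$pct_mis_gt1, 100)

  chain <- summarize_outputs(chain_system())
  expect_equal(tidy(chain)$min_input, 1L)
  expect_equal(tidy(chain)$mis_size, 1L)

  # aggregates recomputable from per-output rows
  sys <- random_fixture(9L)
  smry2 <- summarize_outputs(sys)
  rows2 <- tidy(smry2)
  feas <- rows2[!rows2$infeasible & !rows2$constitutive, ]
  expect_equal(glance(smry2)$mean_min_input, mean(feas$min_input))
  expect_equal(glance(smry2)$pct_mis_gt1, 100 * mean(feas$mis_size > 1))
})

test_that("summary TSV mirrors the rows with an aggregate footer", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_summary_tsv(summarize_outputs(diamond_system()), f)
  lines <- readLines(f)
  expect_match(lines[1], "^# boolsig")
  expect_equal(strsplit(lines[2], "\t")[[1]][1:4],
               c("output", "name", "min_input", "mis_size"))
  expect_match(lines[3], "^O\tO\t1\t2")
  expect_true(any(grepl("^# pct_mis_gt1", lines)))
})
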