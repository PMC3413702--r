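# Dependency graph, SCC detection/classification, loop fixes, GML round
# trip and graph statistics.

test_that("dependency_graph follows the antecedent -> consequent rule", {
  g <- dependency_graph(boolean_system(signalling_event("e", "S1", "S2")))
  expect_setequal(igraph::V(g)$name, c("S1", "S2", "e"))
  el <- igraph::as_edgelist(g)
  expect_equal(nrow(el), 2L)
  expect_true(any(el[, 1] == "S1" & el[, 2] == "e"))
  expect_true(any(el[, 1] == "e" & el[, 2] == "S2"))

  # inhibitors sit on the left of the implication: they produce edges too
  gi <- dependency_graph(toy_inhibition_model())
  eli <- igraph::as_edgelist(gi)
  expect_true(any(eli[, 1] == "I" & eli[, 2] == "e1"))

  # worked loop fixture: 10 nodes, 10 edges
  gl <- dependency_graph(toy_loop_model())
  expect_equal(igraph::vcount(gl), 10L)
  expect_equal(igraph::ecount(gl), 10L)
})

test_that("find_sccs detects and classifies the loop fixtures", {
  rep1 <- find_sccs(toy_loop_model())
  expect_equal(nrow(rep1), 1L)
  expect_setequal(rep1$component[[1]],
                  c("X", "r_complex", "X:J", "r_convert", "X:J'", "r_dissoc"))
  expect_equal(rep1$classification, "complex-dissociation")

  expect_equal(nrow(find_sccs(toy_loop_model(curated = TRUE))), 0L)

  cat_rep <- find_sccs(catalysis_system())
  expect_equal(cat_rep$order, 2L)
  expect_equal(cat_rep$classification, "catalysis")

  # acyclic fixtures have no nontrivial SCC
  expect_equal(nrow(find_sccs(random_fixture(2L))), 0L)
})

test_that("find_sccs agrees with a naive mutual-reachability oracle", {
  fixtures <- list(
    toy_loop_model(), mek_erk_model(), catalysis_system(),
    random_system(fixture_spec(n_inputs = 4, n_internal = 8, n_events = 5,
                               planted_catalysis = 2, planted_dissociation = 1,
                               seed = 12)),
    random_fixture(31L))
  for (sys in fixtures) {
    g <- dependency_graph(sys)
    expect_lte(igraph::vcount(g), 60L)
    rep <- find_sccs(g)
    expect_identical(rep$component, naive_scc_components(g))
  }
})

test_that("catalysis fix removes the catalyst output and keeps it required", {
  sys <- catalysis_system()
  comp <- find_sccs(sys)$component[[1]]
  fixed <- apply_catalysis_fix(sys, comp)
  i <- match("r", fixed$events$id)
  expect_setequal(fixed$events$outputs[[i]], "Y")
  expect_true("C" %in% fixed$events$inputs[[i]])
  expect_equal(nrow(find_sccs(fixed)), 0L)
  log <- curation_log(fixed)
  expect_equal(log$kind, "remove-catalyst-output")

  # the catalyst becomes a source after curation (reclassification delta)
  expect_true("C" %in% classify_signals(sys)$internal)
  expect_true("C" %in% classify_signals(fixed)$sources)

  # applying to a non-catalysis order-2 pattern errors
  expect_error(apply_catalysis_fix(sys, c("X", "Y")),
               class = "boolsig_motif_mismatch")
})

test_that("catalysis fix exposes the catalyst as a required system input", {
  # pre-curation the catalyst justifies itself through the order-2 loop, so
  # only X counts as an input; the fix makes C a free input that must be
  # supplied, raising the minimum input for Y from 1 to 2 (the same
  # under-reporting-then-correction pattern as the dissociation loop)
  sys <- catalysis_system()
  fixed <- apply_catalysis_fix(sys, find_sccs(sys)$component[[1]])
  pre <- minimum_input(sys, c(Y = 1))
  expect_equal(pre$objective_value, 1)
  expect_equal(pre$active_inputs, "X")
  post <- minimum_input(fixed, c(Y = 1))
  expect_equal(post$objective_value, 2)
  expect_equal(post$active_inputs, c("C", "X"))
  # cross-check both by brute force
  expect_equal(brute_force_minimal_input_sets(sys, c(Y = 1))$sets, list("X"))
  expect_equal(brute_force_minimal_input_sets(fixed, c(Y = 1))$sets,
               list(c("C", "X")))
})

test_that("dissociation fix removes the recycled reactant, not the formation edge", {
  sys <- toy_loop_model()
  comp <- find_sccs(sys)$component[[1]]
  fixed <- apply_dissociation_fix(sys, comp)
  i <- match("r_dissoc", fixed$events$id)
  expect_equal(fixed$events$outputs[[i]], "J'")
  expect_equal(minimum_input(fixed, c("J'" = 1))$objective_value, 2)
  expect_equal(curation_log(fixed)$kind, "remove-derivation-membership")

  # MEK/ERK motif: phosphorylated product still derivable, recycling gone
  me <- mek_erk_model(curated = TRUE)
  mi <- minimum_input(me, c(pERK = 1))
  expect_equal(mi$status, "optimal")
  expect_setequal(mi$active_inputs, c("upstream_MEK", "upstream_ERK"))
  expect_equal(nrow(find_sccs(me)), 0L)

  # negative control: deleting the formation membership instead lets the
  # complex form without the reactant
  broken <- sys
  j <- match("r_complex", broken$events$id)
  broken$events$inputs[[j]] <- setdiff(broken$events$inputs[[j]], "X")
  broken <- boolean_system(broken$events)
  r <- minimum_input(broken, c("X:J" = 1, I = 0))
  expect_equal(r$status, "optimal")  # X:J without X's upstream input: wrong
  expect_equal(minimum_input(fixed, c("X:J" = 1, I = 0))$status, "infeasible")
})

test_that("ambiguous dissociation motifs require an explicit choice", {
  # two recycled reactants from one dissociation event
  sys <- boolean_system(dplyr::bind_rows(
    signalling_event("rA", "inA", "A"),
    signalling_event("rB", "inB", "B"),
    signalling_event("rC", c("A", "B"), "A:B"),
    signalling_event("rD", "A:B", c("A", "B", "P"))))
  comp <- find_sccs(sys)$component[[1]]
  err <- tryCatch(apply_dissociation_fix(sys, comp),
                  boolsig_ambiguous_motif = function(e) e)
  expect_s3_class(err, "boolsig_ambiguous_motif")
  expect_gte(nrow(err$candidates), 2L)
  fixed <- apply_dissociation_fix(sys, comp,
                                  recycled = c(event = "rD", signal = "A"))
  expect_setequal(fixed$events$outputs[[match("rD", fixed$events$id)]],
                  c("B", "P"))
})

test_that("curation strictly decreases edges and clears planted SCCs", {
  for (seed in c(1L, 7L, 19L)) {
    sys <- random_system(fixture_spec(
      n_inputs = 4, n_internal = 8, n_events = 5,
      planted_catalysis = 1 + seed %% 2, planted_dissociation = 1,
      seed = seed))
    n_scc <- nrow(find_sccs(sys))
    expect_equal(n_scc, 1L + seed %% 2 + 1L)
    edges_before <- igraph::ecount(dependency_graph(sys))
    cured <- curate_sccs(sys)
    expect_lt(igraph::ecount(dependency_graph(cured)), edges_before)
    expect_equal(nrow(find_sccs(cured)), 0L)
    expect_gte(nrow(curation_log(cured)), n_scc)
  }
})

test_that("graph_statistics matches hand computation on the single-event system", {
  st <- graph_statistics(boolean_system(signalling_event("e", "S1", "S2")))
  expect_equal(st$order, 3)
  expect_equal(st$size, 2)
  expect_equal(st$max_indegree, 1)
  expect_equal(st$max_outdegree, 1)
  expect_equal(st$n_sources, 1)
  expect_equal(st$n_sinks, 1)
  expect_equal(st$n_scc, 0)
  expect_equal(st$char_path_length, 4 / 3)  # paths: S1->e (1), S1->S2 (2), e->S2 (1)
  expect_equal(st$diameter, 2)
  expect_equal(st$radius, 1)

  lp <- graph_statistics(toy_loop_model())
  expect_equal(lp$order, 10)
  expect_equal(lp$size, 10)
  expect_equal(lp$n_scc, 1)
})

test_that("GML export/import round trip is the identity and edits map to statements", {
  tl <- toy_loop_model()
  f <- withr::local_tempfile(fileext = ".gml")
  export_gml(tl, f)
  first <- readLines(f)
  export_gml(tl, f)
  expect_identical(readLines(f), first)  # byte-identical re-export

  back <- import_curated_gml(tl, f)
  expect_identical(statements(back), statements(tl))

  # igraph parses the emitted dialect (format cross-check)
  ig <- igraph::read_graph(f, format = "gml")
  expect_equal(igraph::vcount(ig), 10)
  expect_equal(igraph::ecount(ig), 10)

  # deleting the r_dissoc -> X edge reproduces the dissociation fix
  g <- dependency_graph(tl)
  nm <- igraph::V(g)$name
  src_id <- which(nm == "r_dissoc") - 1L
  tgt_id <- which(nm == "X") - 1L
  lines <- readLines(f)
  starts <- which(lines == "  edge [")
  drop <- NULL
  for (b in starts) {
    if (grepl(paste0("source ", src_id, "$"), lines[b + 1]) &&
        grepl(paste0("target ", tgt_id, "$"), lines[b + 2])) {
      drop <- b:(b + 3)
    }
  }
  writeLines(lines[-drop], f)
  edited <- import_curated_gml(tl, f)
  expect_identical(statements(edited),
                   statements(toy_loop_model(curated = TRUE)))
})

test_that("GML node deletion removes the signal and its incident statements", {
  sys <- diamond_system()
  f <- withr::local_tempfile(fileext = ".gml")
  export_gml(sys, f)
  lines <- readLines(f)
  # delete node B and its incident edge blocks
  g <- dependency_graph(sys)
  b_id <- which(igraph::V(g)$name == "B") - 1L
  node_starts <- which(lines == "  node [")
  for (b in node_starts) {
    if (grepl(paste0("^    id ", b_id, "$"), lines[b + 1])) {
      lines <- lines[-(b:(b + 5))]
      break
    }
  }
  edge_starts <- which(lines == "  edge [")
  keep <- rep(TRUE, length(lines))
  for (b in edge_starts) {
    if (grepl(paste0("source ", b_id, "$"), lines[b + 1]) ||
        grepl(paste0("target ", b_id, "$"), lines[b + 2])) {
      keep[b:(b + 3)] <- FALSE
    }
  }
  writeLines(lines[keep], f)
  cut <- import_curated_gml(sys, f)
  expect_false("B" %in% cut$signals$id)
  # e2's activation statement was incident to B, so the whole event goes
  expect_false("e2" %in% cut$events$id)
  der <- Filter(function(s) s$kind == "output-derivation", statements(cut))
  expect_equal(der[[1]]$pos, "e1")
})

test_that("GML errors carry line context", {
  tl <- toy_loop_model()
  f <- withr::local_tempfile(fileext = ".gml")
  export_gml(tl, f)
  lines <- readLines(f)
  lines[grepl('name "X"', lines)] <- '    name "XX_unknown"'
  writeLines(lines, f)
  err <- tryCatch(import_curated_gml(tl, f), boolsig_gml_error = function(e) e)
  expect_s3_class(err, "boolsig_gml_error")
  expect_match(conditionMessage(err), "line [0-9]+")

  writeLines(c("graph [", "  node ["), f)
  expect_error(import_curated_gml(tl, f), class = "boolsig_gml_error")
})
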