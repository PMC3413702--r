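# Small systems and oracles shared across test files.

diamond_system <- function() {
  boolean_system(dplyr::bind_rows(
    signalling_event("e1", "A", "O"),
    signalling_event("e2", "B", "O")))
}

chain_system <- function() {
  boolean_system(dplyr::bind_rows(
    signalling_event("e1", "A", "B"),
    signalling_event("e2", "B", "O")))
}

catalysis_system <- function() {
  # C catalyses conversion of X to Y and is written as input and output
  boolean_system(signalling_event("r", inputs = c("C", "X"),
                                  outputs = c("C", "Y")))
}

# A stylised two-route activation model (synthetic stand-in, built for the
# shape of a mixed active/inactive target query): one output reachable via a
# costimulatory receptor route and via a receptor-ligand + kinase route,
# with a separate input driving the output that must stay inactive.
two_route_tcell_like <- function() {
  boolean_system(dplyr::bind_rows(
    signalling_event("eA", "CD28", "Rac"),
    signalling_event("eB", "Rac", "Jnk"),
    signalling_event("eC", c("TCRlig", "Lck"), "TCRp"),
    signalling_event("eD", "TCRp", "Jnk"),
    signalling_event("eE", "CD45", "Erk")))
}

# independent SCC oracle: u and v share a component iff mutually reachable
naive_scc_components <- function(g) {
  d <- igraph::distances(g, mode = "out")
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  mutual <- is.finite(d) & is.finite(t(d))
  diag(mutual) <- TRUE
  seen <- rep(FALSE, n)
  comps <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    members <- which(mutual[i, ] & mutual[, i])
    seen[members] <- TRUE
    loops <- igraph::which_loop(g)
    has_self <- any(loops) &&
      nodes[i] %in% igraph::ends(g, igraph::E(g))[loops, 1L]
    if (length(members) >= 2L || has_self) {
      comps[[length(comps) + 1L]] <- sort(nodes[members])
    }
  }
  comps[order(vapply(comps, `[`, "", 1L))]
}

# exhaustive check that every MinimalInputSets invariant holds for a result
expect_mis_invariants <- function(mis, system, target) {
  sets <- mis$sets
  if (length(sets) >= 2L) {
    for (i in seq_along(sets)) {
      for (j in seq_along(sets)) {
        if (i == j) next
        expect_true(length(setdiff(sets[[i]], sets[[j]])) > 0L)
      }
    }
  }
  ctx <- boolsig:::oracle_context(system)
  inputs <- classify_signals(system)$sources
  for (s in sets) {
    expect_true(boolsig:::target_achievable(system, s, target, ctx = ctx))
    for (drop in s) {
      expect_false(boolsig:::target_achievable(system, setdiff(s, drop),
                                               target, ctx = ctx))
    }
  }
  invisible(TRUE)
}

# acceptance-world random fixture (chosen once; see package notes)
random_fixture <- function(seed) {
  random_system(fixture_spec(
    n_inputs = 3L + seed %% 6L,
    n_internal = 8L + seed %% 5L,
    n_events = 4L + seed %% 7L,
    p_inhibit = if (seed %% 2L == 1L) 0.35 else 0,
    seed = seed))
}

write_biopax_fixture <- function(path, body) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    '         xmlns:owl="http://www.w3.org/2002/07/owl#"',
    '         xmlns:bp="http://www.biopax.org/release/biopax-level3.owl#"',
    '         xml:base="http://example.org/model#">',
    '  <owl:Ontology rdf:about=""/>',
    body,
    '</rdf:RDF>'), path)
  path
}

bp_protein <- function(id, name = id) {
  sprintf('<bp:Protein rdf:ID="%s"><bp:displayName>%s</bp:displayName></bp:Protein>',
          id, name)
}

bp_reaction <- function(id, left, right) {
  paste0('<bp:BiochemicalReaction rdf:ID="', id, '">',
         paste(sprintf('<bp:left rdf:resource="#%s"/>', left), collapse = ""),
         paste(sprintf('<bp:right rdf:resource="#%s"/>', right), collapse = ""),
         '</bp:BiochemicalReaction>')
}

bp_control <- function(id, type, controller, controlled,
                       class = "Control") {
  sprintf(paste0('<bp:%s rdf:ID="%s"><bp:controlType>%s</bp:controlType>',
                 '<bp:controller rdf:resource="#%s"/>',
                 '<bp:controlled rdf:resource="#%s"/></bp:%s>'),
          class, id, type, controller, controlled, class)
}
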