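# Compilation of signalling events into the Boolean statement system.

test_that("compile_statements produces one activation per event and one derivation per produced signal", {
  # single event S1 -> S2
  st <- compile_statements(signalling_event("e1", "S1", "S2"))
  expect_length(st, 2L)
  act <- st[[1]]
  expect_equal(act$kind, "event-activation")
  expect_equal(act$consequent, "e1")
  expect_equal(act$pos, "S1")
  expect_equal(act$neg, character())
  der <- st[[2]]
  expect_equal(der$kind, "output-derivation")
  expect_equal(der$consequent, "S2")
  expect_equal(der$pos, "e1")

  # empty event list
  empty <- as_events(tibble::tibble(id = character(), inputs = list(),
                                    outputs = list()))
  expect_length(compile_statements(empty), 0L)

  # two events producing S3: single derivation with both producers
  st2 <- compile_statements(dplyr::bind_rows(
    signalling_event("e1", "A", "S3"),
    signalling_event("e2", "B", "S3")))
  expect_length(st2, 3L)
  ders <- Filter(function(s) s$kind == "output-derivation", st2)
  expect_length(ders, 1L)
  expect_equal(ders[[1]]$consequent, "S3")
  expect_equal(ders[[1]]$pos, c("e1", "e2"))
})

test_that("compile errors: duplicate event id and empty output set", {
  dup <- tibble::tibble(id = c("e1", "e1"), inputs = c("A", "B"),
                        outputs = c("X", "Y"))
  expect_error(as_events(dup), class = "boolsig_duplicate_event")
  expect_error(signalling_event("e1", "A", character()),
               class = "boolsig_invalid_event")
})

test_that("statement-count conservation and variable bijection hold on random systems", {
  for (seed in c(2L, 11L, 23L)) {
    sys <- random_fixture(seed)
    sts <- statements(sys)
    kinds <- vapply(sts, `[[`, "", "kind")
    expect_equal(sum(kinds == "event-activation"), nrow(sys$events))
    produced <- unique(unlist(sys$events$outputs))
    expect_equal(sum(kinds == "output-derivation"), length(produced))
    # exactly one derivation per produced signal, listing all producers
    for (s in produced) {
      der <- Filter(function(x) x$kind == "output-derivation" && x$consequent == s, sts)
      expect_length(der, 1L)
      prods <- sys$events$id[purrr::map_lgl(sys$events$outputs, ~ s %in% .x)]
      expect_setequal(der[[1]]$pos, prods)
    }
    expect_length(intersect(sys$signals$id, sys$events$id), 0L)
    expect_setequal(variables(sys), c(sys$signals$id, sys$events$id))
  }
})

test_that("signal/event id collisions are rejected and self-inhibition warns", {
  expect_error(
    boolean_system(dplyr::bind_rows(
      signalling_event("x", "A", "B"),
      signalling_event("e2", "x", "C"))),
    class = "boolsig_id_clash")
  expect_warning(
    boolean_system(signalling_event("e1", "A", "B", inhibitors = "A")),
    regexp = "permanently inactive")
})

test_that("attach_inhibitors places negative literals correctly and is idempotent", {
  sys <- boolean_system(dplyr::bind_rows(
    signalling_event("e1", "S1", "S2"),
    signalling_event("e2", "A", "S3"),
    signalling_event("e3", "B", "S3")))

  # event-specific: only e1's activation statement gains the literal
  sys1 <- attach_inhibitors(sys, event_inhibitions = list(e1 = "B"))
  acts <- Filter(function(s) s$kind == "event-activation", statements(sys1))
  names(acts) <- vapply(acts, `[[`, "", "consequent")
  expect_equal(acts$e1$neg, "B")
  expect_equal(acts$e2$neg, character())
  expect_equal(acts$e3$neg, character())
  expect_setequal(acts$e1$pos, "S1")

  # general inhibitor of S3: added to both producing events only
  gi <- data.frame(inhibitor = "S2", target = "S3")
  sys2 <- attach_inhibitors(sys, general_inhibitions = gi)
  acts2 <- Filter(function(s) s$kind == "event-activation", statements(sys2))
  names(acts2) <- vapply(acts2, `[[`, "", "consequent")
  expect_equal(acts2$e2$neg, "S2")
  expect_equal(acts2$e3$neg, "S2")
  expect_equal(acts2$e1$neg, character())

  # idempotence and commutation over independent inhibitions
  expect_identical(statements(attach_inhibitors(sys2, general_inhibitions = gi)),
                   statements(sys2))
  ab <- attach_inhibitors(attach_inhibitors(sys, list(e1 = "B")),
                          general_inhibitions = gi)
  ba <- attach_inhibitors(attach_inhibitors(sys, general_inhibitions = gi),
                          list(e1 = "B"))
  expect_identical(statements(ab), statements(ba))

  # no-op cases
  expect_identical(statements(attach_inhibitors(sys)), statements(sys))
  expect_warning(
    boolean_system(signalling_event("e1", "S1", "S2"),
                   general_inhibitions = data.frame(inhibitor = "S1",
                                                    target = "S1")),
    regexp = "no producers")
})

test_that("classify_signals partitions participating signals", {
  # worked loop fixture
  cls <- classify_signals(toy_loop_model())
  expect_equal(cls$sources, c("I", "J"))
  expect_equal(cls$sinks, "J'")
  expect_setequal(cls$internal, c("X", "X:J", "X:J'"))

  # single event
  cls1 <- classify_signals(boolean_system(signalling_event("e", "S1", "S2")))
  expect_equal(cls1$sources, "S1")
  expect_equal(cls1$sinks, "S2")
  expect_length(cls1$internal, 0L)

  # output of e1 and input of e2 is internal
  expect_equal(classify_signals(chain_system())$internal, "B")

  # inhibitor-only signals sit on the input side
  expect_true("I" %in% classify_signals(toy_inhibition_model())$sources)

  # exact cover, pairwise disjoint, on random systems
  for (seed in c(5L, 17L)) {
    sys <- random_fixture(seed)
    cls <- classify_signals(sys)
    parts <- c(cls$sources, cls$sinks, cls$internal)
    expect_equal(anyDuplicated(parts), 0L)
    participating <- unique(c(unlist(sys$events$inputs),
                              unlist(sys$events$catalysts),
                              unlist(sys$events$inhibitors),
                              unlist(sys$events$outputs)))
    expect_setequal(parts, participating)
  }
})

test_that("isolated signals are reported separately", {
  sys <- boolean_system(signalling_event("e", "S1", "S2"),
                        signals = tibble::tibble(id = c("S1", "S2", "lonely"),
                                                 name = c("S1", "S2", "lonely")))
  expect_equal(classify_signals(sys)$isolated, "lonely")
})

test_that("tidy and glance summarize a system", {
  sys <- toy_inhibition_model()
  td <- tidy(sys)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("kind", "consequent", "variable", "sign") %in% names(td)))
  expect_equal(td$sign[td$variable == "I"], "negative")
  gl <- glance(sys)
  expect_equal(gl$n_signals, 3L)
  expect_equal(gl$n_events, 1L)
  expect_equal(gl$n_statements, 2L)
})
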