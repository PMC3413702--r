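---
title: "Boolean signalling models with event-level inhibition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boolean signalling models with event-level inhibition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolsig)
```

## The model

A signalling system is a set of physical entities (proteins, complexes,
small molecules, RNAs) and a set of *signalling events*, each transducing
information from a conjunctive set of active inputs to a set of outputs.
`boolsig` assigns one binary variable per signal (in bijection with the
entities) and one per event, and compiles two statement families:

* an **event-activation** statement per event: the reaction variable `r`
  holds exactly when every required input (upstream signal, catalyst or
  activator — all treated identically as conjunctive requirements) is
  active and no inhibitor of the event is active;
* an **output-derivation** statement per produced signal: the signal holds
  exactly when at least one of the events producing it fires.

Signals never produced by any event have no derivation statement; they are
the free variables (*system inputs*) of every optimization. A signal's role
is decided purely by the event table: consumed-only signals (including
signals that only appear as inhibitors) are inputs, produced-only signals
are *system outputs*, and signals on both sides are *internal nodes*.

### Inhibition semantics

Inhibition is modelled at the event level: an inhibitor prevents specific
events from firing and never deactivates a signal directly. A *general*
inhibitor of a signal — one that blocks signalling by that entity rather
than a particular reaction — is attached to every event producing the
signal. This avoids the incoherence of signal-level inhibition, where one
statement demands a signal active and another demands it inactive. In the
minimal model (`toy_inhibition_model()`: `S1` activates `S2`, inhibited by
`I`) the three characteristic behaviours hold: `S1` active and `I`
inactive gives `S2`; the mere absence of `I` gives nothing; and `S1` and
`I` together remain feasible with `S2` off.

### Why the statements are equivalences

The statements could be encoded as one-way implications or as
equivalences; `boolsig` encodes equivalences. Three observable behaviours
force this choice, and all three are exercised by the test suite:

1. under one-way implications, `¬I → S2`-style transposition would let the
   absence of an inhibitor activate the inhibited signal;
2. with an output fixed active, one-way implications demand no cause, so
   every Minimum Input objective would be trivially 0; under equivalences a
   fixed-active output forces a producing reaction and hence its inputs;
3. the complex-dissociation loop example admits exactly two satisfying
   assignments with its product fixed active — a count that only the
   equivalence reading reproduces.

One consequence worth stating plainly: with equivalences, a signal inside
a cycle can justify itself (see Curation below), and a catalyst written as
both input and output of its reaction is an *internal* node until curated.
The catalysis fix therefore raises the Minimum Input of downstream targets
(the catalyst becomes a system input that must be supplied); this is the
intended correction, not an artefact.

## Integer encoding and the solver

Each statement is rewritten in conjunctive normal form: for
`r ⇔ (x₁ ∧ … ∧ x_k ∧ ¬z₁ ∧ … ∧ ¬z_q)` the clauses `(¬r ∨ xᵢ)`,
`(¬r ∨ ¬zⱼ)` and `(r ∨ ¬x₁ ∨ … ∨ z₁ ∨ …)`; for `s ⇔ (r₁ ∨ … ∨ r_p)` the
clauses `(¬s ∨ r₁ ∨ … ∨ r_p)` and `(s ∨ ¬rᵢ)`. Every clause becomes one
covering constraint `Σ v⁺ + Σ (1 − v⁻) ≥ 1` over binary variables, so CNF
satisfaction and integer feasibility coincide assignment-for-assignment
(verified exhaustively in the tests on systems up to 15 variables).

No exact mixed-integer solver package is available in the target
environment, so the package carries its own small exact back end
(`src/bip.cpp`): depth-first branch and bound over binary variables with
constraint bound propagation at every node. Design points:

* all data are integers; the optimal objective value is exact and unique;
* branching order is fixed (lowest variable index, objective-favourable
  value first) so results are deterministic; among co-optimal assignments
  the first found is kept, and no algorithm in the package depends on
  which witness is returned;
* a node budget (default 10⁷, option `boolsig.node_limit`) turns runaway
  searches into a distinct error — never a silent "infeasible";
* problems generated from statements are canonically ordered (statements
  sorted by consequent), so emitted problems are stable across runs.

For the model sizes this package targets interactively (single pathways,
random benchmark systems of ~150 signals) propagation solves most nodes
directly; the dominant cost in batch analyses is the number of solves, not
the individual solve.

## The three queries

**Minimum Input** fixes the requested signal states, sets the objective to
the sum over system-input variables and minimizes (or maximizes on
request). **Output Maximization** fixes supplied input states — unfixed
inputs are held inactive unless explicitly freed, so "what can these
inputs alone produce?" is the default question — and maximizes the sum
over system outputs; with all inputs fixed the output set is unique and
maximal.

**Minimal Input Sets** enumerates the antichain of distinct minimal input
combinations for a target. Two sets are distinct when each contains a
signal the other lacks. The algorithm solves Minimum Input, then from a
solution with `j` active inputs spawns `j` descendant problems, each
adding one integer cut (one active input forced inactive) while retaining
all ancestor cuts, recursing until every branch is infeasible. The
rejected alternative — cutting with the powerset of the active set — would
spawn `2ⁿ` descendants (`powerset_descendant_count()`); single cuts spawn
`n` and still visit every distinct minimal set, because any minimal set
missed by the current witness must avoid at least one of its members.
Implementation choices:

* **Memoization.** A descendant is identified by its cut set; previously
  seen cut sets are not re-solved. The enumeration tree otherwise revisits
  identical subproblems factorially often.
* **Certification.** Witnesses of minimum cardinality under cuts are
  provably inclusion-minimal, but the result is certified anyway: each
  surviving set is checked feasible (members active, all other inputs
  inactive, target achieved) and minimal (outside inputs fixed inactive,
  requiring strictly fewer active inputs must be infeasible). Superset
  filtering alone cannot certify minimality.
* **Trivial combinations.** If the target is achievable with zero active
  inputs the output is constitutive: the set collection is empty and
  flagged, matching the convention that input-combination counts exclude
  the empty set.
* **Budget.** A per-target solver-call budget (default 10⁶, the order of
  magnitude a full-database batch requires) raises a resource error that
  carries the partial result.
* **Redundant outputs.** Outputs with identical producing-reaction sets
  get identical results, so batch summaries compute once per group and
  copy (`redundant_output_groups()`); the call counter (`solver_calls()`)
  lets tests assert the saving.

The independent oracle `brute_force_minimal_input_sets()` enumerates all
input combinations and tests achievability by direct evaluation of the
statement semantics — topological propagation for acyclic systems (where
the equivalences have a unique solution given the inputs), exhaustive
search over non-input variables for cyclic ones — entirely bypassing the
CNF/integer path. Sequential batch execution is the default and the
contract; any parallel execution must reproduce it exactly.

## Curation

The dependency graph has one node per variable and an edge `(u, v)`
whenever `u` appears in the antecedent of a statement with consequent `v`
(inhibitors included: they sit on the left of the implication). Strongly
connected components of this graph are self-justifying once a member is
fixed active, so they corrupt input-requirement queries. SCC detection
uses igraph's Tarjan-style algorithm; a naive mutual-reachability oracle
cross-checks it in the tests. Only nontrivial components count (order ≥ 2,
or a self-looped singleton) — trivial singletons would make the count
meaningless on any large graph.

Two motifs cover the common cases and are fixed automatically when
unambiguous:

* **Catalysis** (order-2: catalyst `C` both input and output of event
  `r`): remove `C` from the outputs of `r`. `C` stays required and becomes
  a system input.
* **Complex dissociation** (formation → modification → dissociation, with
  the dissociation recycling a reactant): remove the recycled reactant
  from the dissociation event's outputs. The modified product stays
  derivable and complex formation still requires the reactant. Deleting
  the formation edge instead — what a fully automatic depth-first
  loop-breaker may do — would allow the complex to form without its
  reactant, which is why automatic curation is deliberately *not* the
  default posture: ambiguous motifs (several candidate recycled reactants)
  are an error listing the candidates, resolvable by an explicit choice or
  by editing the exported GML externally and re-importing it.

Every curation action strictly removes memberships, never adds; the
dependency graph loses edges and the source/sink classification is
recomputed afterwards (curation can create new inputs and outputs — e.g. a
catalyst surfacing as a required input). All actions are recorded in
`curation_log()`.

### GML round trip

`export_gml()` writes a deterministic, timestamp-free GML file (node id,
variable name, label, class); `import_curated_gml()` diffs the edited file
against the system: a deleted edge removes the corresponding antecedent
literal or derivation membership, a deleted node removes the variable and
every statement incident to it (for a signal: the events that require it —
weakening an event's requirement would violate the strictly-removes rule).
An unedited round trip is the identity on the statement set. The package
writes and parses its own small GML subset because the available library
writer embeds a timestamp (breaking byte-stable output) and cannot report
line-level errors; tests confirm igraph parses the emitted files.

### Graph statistics

`graph_statistics()` reports order and size over all nodes; degree maxima
and source/sink counts over signal nodes; the nontrivial SCC count; mean
undirected neighbour count; and directed path statistics over finite
shortest paths only (characteristic path length over ordered reachable
non-self pairs, diameter as the maximum, radius as the minimum positive
out-eccentricity over nodes that reach at least one other node). The
radius convention is the one under which sparse directed compilations of
pathway data report radius 1 — a node one step from everything it can
reach always exists here (any input feeding a terminal-producing event);
other tools may define eccentricity differently.

## Synthetic data

`random_system()` generates layered acyclic systems: events draw 1–k
conjunctive inputs from already-available signals (system inputs first,
then earlier products), produce fresh or later-ranked signals (the 30%
reuse rate gives some outputs multiple producers, hence nontrivial minimal
input sets), and gain an event-specific inhibitor with probability
`p_inhibit`. Defaults (50 inputs, up to 100 internal signals, 50 events,
≤3 inputs/event, `p_inhibit` 0.2) match the scale of randomly generated
benchmark networks in this literature — on the order of 150 signals and 50
events. Cycles enter *only* through planted motifs (catalysis or
dissociation loops inserted verbatim with fresh ids), so the expected SCC
count and classification are exact ground truth. Generation is a pure
function of the spec including its seed.

What the generator does **not** emulate: realistic degree distributions,
crosstalk between functional pathways, shared complexes, or general
inhibitions. A green oracle-equivalence test therefore establishes
correctness of the enumeration on conjunction/disjunction/negation
structures of realistic size and shape, not fidelity to any particular
database's topology.

## Numerical and edge-case conventions

* Event member sets are canonically sorted everywhere; serialization
  (SIGTXT, GML, LP) is deterministic and re-runs are byte-identical.
* Events with no inputs are legal and constitutive (their activation
  statement is a unit clause); a signal inhibiting an event it feeds is
  accepted with a warning (the event is permanently inactive).
* General inhibitions are materialized into the inhibitor sets of the
  producing events at attach time; attachment is idempotent and
  independent inhibitions commute. A general inhibition whose target has
  no producers is a warning and a no-op.
* Multiple outputs of one event share a single reaction variable.
* Batch summaries report both averaging conventions for the mean Minimum
  Input (over all outputs, and over feasible non-constitutive outputs
  only), since either may be wanted when comparing datasets.
* BioPAX mapping (Level 3 only; Level 2 is rejected explicitly):
  conversions become events with `left` as inputs and `right` as outputs;
  activating catalyses add their controllers to the conjunctive inputs;
  inhibitory controls of a reaction become event inhibitors; inhibitory
  modulations of a catalysis are event-specific by default or general
  inhibitions of the reaction's outputs under `modulation = "general"`;
  the control-type vocabulary is a configurable prefix list. Complexes
  are identified by their component multiset, and complex activity never
  implicitly activates the components.

## Limitations

Events are timeless: the model describes stable and semi-stable states,
not trajectories, so oscillations flatten into the union of their states
and kinetic competition between events is invisible unless expressed as
explicit inhibition or resolved during curation. Stoichiometry, quantities
and compartments are out of scope. The bundled solver is exact but not an
industrial MILP engine; genome-scale batch enumerations are supported by
the budget/partial-result machinery rather than by raw speed.
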