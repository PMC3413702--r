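# boolsig

Boolean modelling of cell signalling networks by exact integer programming.

Curated signalling databases (Reactome, Panther, NCI-Nature) describe
thousands of reactions but carry no kinetic parameters, so differential-
equation models cannot scale to them. `boolsig` takes the constraint-based
route: it compiles a set of *signalling events* — each transducing a
conjunctive set of active input signals (including catalysts) into a set of
output signals — into a system of Boolean statements, translates the
statements into a binary integer program, and answers steady-state queries
exactly.

Every signal `s` and event `r` is a 0/1 variable. Each event contributes an
activation statement and each produced signal one derivation statement,
both read as equivalences:

    r  ⇔  x₁ ∧ … ∧ x_k ∧ ¬z₁ ∧ … ∧ ¬z_q      (inputs x, inhibitors z)
    s  ⇔  r₁ ∨ … ∨ r_p                        (reactions producing s)

The distinctive choice is that **inhibition acts on events, not signals**:
an inhibitor appears only as a negated literal in the activation condition
of the events it blocks. The absence of an inhibitor is never by itself
sufficient to activate anything, and the co-occurrence of activator and
inhibitor leaves the system feasible (with the event off) instead of
logically incoherent.

The statements are rewritten in conjunctive normal form; each clause
becomes the covering constraint `Σ v⁺ + Σ (1−v⁻) ≥ 1` over binary
variables. Three query types are provided:

* **Minimum Input** — fewest active system inputs consistent with a fixed
  target state (`minimum_input()`);
* **Output Maximization** — all outputs generable from given input states
  (`output_maximization()`);
* **Minimal Input Sets** — the full antichain of distinct, individually
  minimal input combinations achieving a target, enumerated with
  single-variable integer cuts and certified minimal
  (`minimal_input_sets()`, with `brute_force_minimal_input_sets()` as an
  independent oracle).

Because the statements are equivalences, cycles in the dependency graph are
self-justifying: a complex-formation/dissociation loop can "produce" its
own reactant, making Minimum Input under-report. `find_sccs()` detects the
strongly connected components, classifies the two common biological motifs
(catalysis written as input-and-output; complex dissociation recycling a
reactant) and `apply_catalysis_fix()` / `apply_dissociation_fix()` /
`curate_sccs()` resolve them; anything ambiguous goes through a
deterministic GML round trip (`export_gml()` → edit in Cytoscape →
`import_curated_gml()`).

Models come from BioPAX Level 3 (`read_biopax()`), the plain-text SIGTXT
format (`read_sigtext()`), in-memory event tables (`signalling_event()`,
`as_events()`), or deterministic generators (`toy_loop_model()`,
`toy_inhibition_model()`, `mek_erk_model()`, `random_system()`).

## Worked example

The classic curation example: `I` produces `X`; `X` and `J` form the
complex `X:J`; the complex is converted to `X:J'` and dissociates into the
product `J'` plus recycled `X`.

```r
library(boolsig)
events <- dplyr::bind_rows(
  signalling_event("r_X",       inputs = "I",         outputs = "X"),
  signalling_event("r_complex", inputs = c("X", "J"), outputs = "X:J"),
  signalling_event("r_convert", inputs = "X:J",       outputs = "X:J'"),
  signalling_event("r_dissoc",  inputs = "X:J'",      outputs = c("X", "J'")))
sys <- boolean_system(events)
sys
#> <boolean_system> 6 signals, 4 events, 8 statements
#>   inputs: 2  outputs: 1  internal: 3  general inhibitions: 0

find_sccs(sys)
#> # A tibble: 1 × 3
#>   component order classification
#> 1 <chr [6]>     6 complex-dissociation

minimum_input(sys, c("J'" = 1))$active_inputs
#> [1] "J"
```

One input suffices — wrongly, because the recycling edge `r_dissoc → X`
lets the loop supply its own `X`. Curation removes that derivation
membership, after which both inputs are required:

```r
cured <- curate_sccs(sys)
mi <- minimum_input(cured, c("J'" = 1))
mi
#> <solve_result> optimal, objective 2, 10 active variables
mi$active_inputs
#> [1] "I" "J"
```

`summarize_outputs()` tabulates Minimum Input and Minimal-Input-Set size
for every system output (here the single output `J'` needs 2 inputs and has
exactly one activating combination):

```r
glance(summarize_outputs(cured))
#> # A tibble: 1 × 6
#>   n_outputs mean_min_input median_min_input mean_min_input_all median_mis_size
#> 1         1              2                2                  2               1
```

## Acceptance script

`scripts/acceptance.R` rebuilds the loop model above from scratch with the
installed package, solves the uncurated Minimum Input problem for `J'`
active, and writes the measured objective as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
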