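---
title: "Task-driven reconstruction of context-specific metabolic models and antimetabolite screening"
author: "tinitr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-driven reconstruction and antimetabolite screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tinitr)
```

## The problem

A genome-scale metabolic model (GEM) describes every metabolic reaction a
cell *could* catalyse: a stoichiometric matrix $S$, flux bounds, and
gene–protein–reaction (GPR) rules linking reactions to the genes encoding
their enzymes.  A given cell type or patient tumour expresses only part
of that repertoire.  Context-specific reconstruction asks: *which
sub-network of the reference GEM is active in this sample?*

Two requirements pull in opposite directions.  The sub-network should
agree with protein evidence (include reactions whose enzymes were
detected, exclude those whose enzymes stain negative), and it should be
*functional* — able to perform the metabolic tasks every cell of that
kind must perform: regenerate ATP from substrates, re-oxidise NADH,
synthesise amino acids, nucleotides and lipids, and, for proliferating
cells, produce biomass.  Evidence alone yields disconnected "snapshot"
networks that cannot simulate; functionality alone ignores the data.
Task-driven reconstruction (the tINIT algorithm) solves the trade-off
explicitly, and the resulting patient-specific models support a concrete
downstream question: which metabolites, if their consumption were blocked
by a structural-analog drug (an antimetabolite), would stop tumour growth
in every patient while leaving the core functions of healthy cell types
intact?

## Metabolic tasks

A task states a conversion contract checked at steady state on an
otherwise *closed* system: all of the model's own exchange reactions are
shut, temporary uptake reactions supply only the task's permitted inputs,
temporary sinks demand its outputs, and optional equation rows enforce a
net conversion (e.g. ATP hydrolysis, standing in for an energy demand the
network must sustain).  Feasibility of the resulting linear program
decides the task.  Closing the system matters: with open exchanges, any
product could be imported and every task would be trivially satisfiable.

Design choices worth knowing:

* "Production" means a sink flux of at least `activation_epsilon`
  (default `1e-4` flux units).  Strict positivity is solver-fragile; a
  small explicit threshold is robust and configurable.
* Equation rows compile to one temporary lumped reaction forced to carry
  at least `activation_epsilon`; a reversible equation is tried in both
  orientations.
* Negative controls (`should_fail` tasks, e.g. ATP from nothing) pass
  exactly when the conversion is *infeasible*; a task list meant to be
  universal needs them to catch mass- or energy-creating model defects.
* A task metabolite absent from a model makes the task infeasible with
  reason `"unmapped metabolite"` rather than raising an error, so draft
  models missing species are handled uniformly.  A merely *permitted*
  flow (lower bound 0) of an absent metabolite is a no-op: the program
  with that never-used column is identical to the program without it.
* Task metabolites may be named compartment-agnostically; all instances
  are pooled through a collector row so bounds apply to the total flow.

The package ships a representative 56-task library (`tasks_core56.tsv`,
four categories: energy and redox, internal conversions, substrate
utilization, biosynthesis of products, including three negative controls)
plus a growth task (`task_growth.tsv`) appended when reconstructing
proliferating cells, together with a curated core network
(`core_model()`) that performs all of them.  Both are authored for this
package as schematic stand-ins: the chemistry is lumped (single reactions
for whole pathways; redox/energy stoichiometry simplified but cycle-safe,
so nothing can create ATP, reducing power or mass from nothing), and the
task list mirrors the structure, not the verbatim content, of curated
human task collections.

## The three-step reconstruction

`tinit()` reconstructs a context model from a reference model, a
per-reaction score vector and a task list.

**Step 1 — task-essential reactions** (`find_essential_reactions()`).
A reaction is essential if removing it from the reference makes at least
one task infeasible.  These reactions must be in any functional model, so
they are forced into the selection.  Note this is not a minimal
functional set: where isozymes or alternative pathways exist, none of the
redundant reactions is essential.  The implementation prunes candidates
to reactions that can carry flux under a task's constraints (accumulated
from optimiser witnesses), which is provably equivalent to the plain
sweep — a reaction that cannot carry flux cannot change feasibility — and
the equivalence is asserted by a test, not assumed.  The reference must
itself pass every non-control task; if it does not, the error names the
failing tasks, because no amount of gap-filling can repair a reference
that *is* the universe.

**Step 2 — score-maximising selection** (`solve_selection_milp()`).
The INIT-style mixed-integer program selects the reaction set with
maximal summed evidence score subject to every selected reaction carrying
flux in one common steady-state distribution:

* binary $y_i$ per reaction (two per reversible reaction when
  bidirectional flux is forbidden), fluxes split into non-negative
  forward/backward parts;
* coupling $v_i \le M y_i$ with `big_M` = 1000, and
  $v_i \ge \varepsilon y_i$ for positively scored and required reactions,
  so selection implies use;
* $y^{fwd}_i + y^{bwd}_i \le 1$ per reversible reaction
  (`forbid_bidirectional_flux`, default on).  Without it, a reversible
  reaction can "activate" itself with a cancelling forward/backward flux
  pair, letting disconnected loops ride into the model — the artifact
  this constraint removes (`test-tinit.R` demonstrates it directly);
* optionally $S v = a$, $a \ge 0$ (`allow_net_production`, the behaviour
  of the original INIT formulation), with accumulation penalised at
  `net_production_penalty` (default 1; the historical value is not
  documented anywhere, so a neutral unit penalty is used) per unit.

**Step 3 — sequential gap-filling** (`gapfill_task()`).  Each task is
tested on the selected network in task-list order; a failing task is
repaired by the minimum-cardinality set of reference reactions whose
addition makes it feasible (a set-cover MILP).  Per-task additions are
recorded in the fit object so order effects are auditable; because step 2
already contains every essential reaction, the draft is nearly functional
and gap-fills are small, which is also why order rarely matters.
Cardinality is unweighted by default — weighting by evidence is possible
but the additions are forced by functionality, not evidence, so a neutral
count is the cleaner default.

The growth task takes part in step 1 like any other task by default;
`exclude_from_essential` opts specific tasks out (they are then enforced
only through gap-filling).

Determinism: equally optimal selections are resolved by a secondary
lexicographic objective (prefer lower reaction index) solved as a second
MILP constrained to the optimal score (`deterministic_ties`, default on).
This also cleans up zero-score reactions that could otherwise be toggled
freely, so repeated runs return identical models.

## Evidence scoring

Ordinal immunohistochemistry calls (strong / moderate / weak / negative,
plus missing) enter as an `evidence_matrix`.  Processing order follows
the biological workflow: impute missing *levels* from the cohort first,
then map levels to scores, then aggregate through GPR rules.

* **Imputation** (`impute_missing()`): a gene missing in one sample gets
  the median of its non-missing ordinal levels across the other samples.
  The median of an even count needs a tie rule on an ordinal scale; the
  package keeps the midpoint when it is integral and rounds it *down*
  otherwise (strong+weak gives moderate; strong+moderate gives moderate,
  not an impossible 2.5).  Any fixed rule would do; this one never
  invents a level above both observations and is verified exhaustively
  against a direct-sort oracle over all small cohorts.
* **Level scores** (`score_mapping()`): defaults strong = +20,
  moderate = +15, weak = +10, negative = −8, missing-after-imputation =
  −2.  Detected levels give graded positive evidence; a negative stain is
  stronger evidence against than mere absence of measurement.  The exact
  magnitudes used for published reconstructions are not recorded
  anywhere, so these defaults follow the spirit of protein-atlas-weighted
  network inference and are fully configurable.
* **GPR aggregation** (`reaction_scores()`): OR = max (one isozyme
  suffices), AND = min (a complex needs all subunits) — the community
  convention.  Reactions without a rule (transport, spontaneous) default
  to 0: no evidence either way.

## The antimetabolite screen

`block_metabolite()` emulates an antimetabolite: the analog inhibits
every enzyme using the metabolite as substrate, so each consuming
reaction direction — pooled over compartments, since the analog does not
respect compartment labels — is constrained to zero flux (forward
consumers lose their forward direction; reversible reactions consuming it
backwards lose the backward direction).  Blocking is provably equivalent
to deleting those directions, and the test suite checks that equivalence
against a model-rebuilding oracle.

`screen_antimetabolites()` iterates over every metabolite name in the
tumour panel: a candidate is *effective* in a tumour model if blocking
makes the growth task infeasible (a binary readout — the screen asks
whether proliferation is possible at all, not how fast); it is
*toxicity-flagged* if blocking newly breaks any energy-and-redox task in
any healthy model (those functions are central to all cells, so their
loss is disqualifying, while other healthy-task failures are reported but
left to the analyst); and it can be excluded as a *pool metabolite* by
name patterns (lumped pool species are not realistic drug mimics).
Baselines matter: only tasks a healthy model passes unblocked can count
as newly broken, and tumour models that cannot grow unblocked are
reported and skipped rather than silently counted.

Running the same screen on a single population-average model and on the
personalised panel exposes the generic model's false positives:
`screen_discrepancy()` returns candidates the generic screen proposes
that fail to disable growth in every individual model (on the shipped
panel fixture, the bypass-carrying patient rescues one such candidate).

## The solver

No linear- or mixed-integer-programming library is part of this
package's dependency footprint; the programs here are small and
structured, so the package carries its own dense solver:

* a bounded-variable revised primal simplex (C++/Armadillo) with
  two-phase start, geometric-mean equilibration (scales rounded to powers
  of two), an explicitly maintained basis inverse with periodic
  refactorisation, and a Harris-style two-pass ratio test that picks the
  numerically best pivot among near-tied minimal ratios.  Degenerate
  stalls switch to Bland's rule (with the strict minimal ratio, as the
  anti-cycling guarantee requires); the bounded per-pivot infeasibility
  the relaxed ratio test admits is cleaned up by refactorising and
  resuming at phase end.  A numerically singular basis triggers one
  paranoid retry with per-pivot refactorisation.
* branch-and-bound over that LP for the MILPs, depth-first, branching on
  the most fractional binary.  The integrality tolerance is set below
  $\varepsilon / M$: with big-M coupling, a relaxation can park a binary
  at exactly $\varepsilon/M$ (about $10^{-7}$ at the defaults), which a
  loose tolerance would wrongly accept as integral.

Every numeric knob lives in `solver_options()`: `activation_epsilon`
(1e-4), `big_M` (1000, comfortably above any attainable flux at the
default bounds), `mip_gap` (1e-6), and optional time limit.  On all
enumerable fixtures the MILP optimum is checked for exact agreement with
a brute-force subset enumeration, and gap-fill cardinality with a
by-size search.

## What the synthetic generators emulate — and what they do not

`random_reference()` plants one substrate-to-product conversion chain per
task plus matching exchanges, then adds distractors: dead ends, redundant
parallel routes, and cross-chain shortcuts.  Chains carry single-gene
rules so evidence maps invertibly to reactions; distractors carry their
own genes.  `simulate_evidence()` stains planted genes detected (with a
per-gene baseline level and per-sample wobble), distractor genes
negative, and injects missing cells at a configurable rate while
guaranteeing every gene is observed somewhere in the cohort, so median
imputation is always defined.  Under this construction the planted
context is the unique selection optimum, which is what makes exact
recovery a meaningful end-to-end assertion.

These fixtures are statistical and topological stand-ins.  They do not
reproduce the scale (thousands of reactions), compartmental organisation,
cofactor coupling, multi-gene rules or evidence noise structure of a real
genome-scale reconstruction, and the shipped core network is schematic
chemistry.  Passing tests therefore demonstrate algorithmic correctness
(optimality, functionality guarantees, classification logic), not
biological fidelity of any particular reconstruction.

## Problem sizes and default study conditions

The deterministic checks run at sizes where exhaustive enumeration is
exact: random fixtures of 12–14 reactions (brute force over all $2^n$
subsets), panels of 3 tumour + 2 healthy toy models, evidence cohorts of
6 samples with a 10% missing rate, 100 fixture seeds for the oracle
comparison and 50 for planted recovery.  The curated core network (60
reactions, 57 tasks) exercises the full pipeline at a scale where the
solver's numerical behaviour — degeneracy, big-M conditioning — is
non-trivial.

## Known limitations

* The screen is binary (growth feasible or not); partial inhibition,
  dose–response and pharmacokinetics are out of scope.
* Blocking pools compartments by metabolite *name*; models whose naming
  does not encode chemical identity need the configurable compartment
  tag patterns of `gem_model()`/`read_sbml()`.
* The dense solver is sized for networks of up to a few hundred
  reactions; genome-scale MILPs (thousands of binaries) need an
  industrial solver backend.
* Sequential gap-filling is order-dependent in principle; the per-task
  additions recorded in the fit make any such effect visible.

## A worked run

```{r toy}
toy <- toy_network()
fit <- tinit(toy$model, toy$scores, toy$tasks)
fit
summary(fit)
```

```{r screen}
tasks <- c(parse_task_table(system.file("extdata", "tasks_core56.tsv",
                                        package = "tinitr")),
           parse_task_table(system.file("extdata", "task_growth.tsv",
                                        package = "tinitr")))
m <- core_model()
print(check_tasks(m, tasks))
```
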