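---
title: "Bounceback-controlled amoeba search: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounceback-controlled amoeba search: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amoebacsp)
```

## The model

The engine simulates a coupled system of 2N units, two per decision
variable. Unit (i, v) embodies the hypothesis "variable i takes value v"
and carries a saturating accumulator X(i,v) with values in {-1, 0, 1},
abstracting the volume displacement of a pseudopod-like branch: supplied
resources push it up one level per step, starvation pulls it down, and it
saturates at the ends.

Resource supply is stochastic and *bounceback-controlled*. A bounceback
rule is a conditional suppression derived from a constraint: when every
unit in its condition sits at X = 1, the rule fires and blocks its target
unit with the intensity assigned to the rule's family. Intensities of
multiple firing rules on one target combine by noisy-OR,
`s = 1 - prod(1 - sigma_r)`, which reduces to a plain OR in the binary
case. The per-unit supply probability interpolates between two globals,

p(s) = (1 - s) * p_free + s * p_blocked,

so an unblocked unit is supplied with probability `p_free` and a fully
blocked one with `p_blocked`.

The decoded assignment is read off the accumulators: variable i takes
value v when unit (i, v) is at 1 while its opponent is at or below 0;
ambiguous configurations keep the previous value. All updates are fully
synchronous: signals are computed from X(t), resources sampled, X(t+1)
formed, and the assignment re-decoded — every quantity at t+1 depends only
on the state at t, matching the model's time indexing of signals (a firing
condition at t blocks supply at t+1).

A state is *stable* when every X = 1 unit is unblocked, every X <= 0 unit
is blocked, and every variable expresses a value (at least one unit at 1).
The third condition is this package's refinement: without it, a variable
can be squeezed down on both sides by rules firing from *other* variables,
and the criterion would certify a state whose decoded value for that
variable is a stale memory of the readout rule rather than anything the
unit state expresses. Such squeezed states persist for a while yet decode
to arbitrary, generally constraint-violating assignments; with the
refinement (and the mutual-suppression rules below) one can show that
stable states under binary intensities coincide exactly with
constraint-satisfying assignments, which the long-run tests confirm
empirically on the worked instance.

## SAT frontend

Each clause of width k compiles to k `CLAUSE` rules: for a literal L, the
condition collects the units asserting that every *other* literal of the
clause is violated, and the target is the unit that would violate L
itself. A unit clause degenerates to an empty condition, which fires
unconditionally; this is the only sound rendering (a conditional variant
keyed on the opposing unit never fires once that unit has been driven
down, leaving the wrong polarity as a stable fixed point).

Each variable additionally receives two `CONTRA` rules — each unit blocks
its opponent. These are needed for two reasons: the decode requires the
opposing accumulator to be at or below 0 before a variable commits, and
the stability criterion requires down units to be blocked by something.
Without them the system can park at X(i,0) = X(i,1) = 1 indefinitely.

```{r}
f <- amoeba_demo_formula()
brute_force_solutions(f)
res <- amoeba_sat(f, amoeba_config(max_steps = 50000, seed = 42))
res$steps
```

## Supply probabilities

The two supply probabilities are the model's only free dynamical
parameters; the sources describe them only as "high" (free) and "low"
(blocked). Their values matter a great deal, and the package's defaults,
`p_free = 0.88` and `p_blocked = 0.002`, come from a two-dimensional pilot
calibration on uniform random 3-SAT at N = 50 (grids over p_free in
0.5–0.99 and p_blocked in 0.0002–0.3, scored by solve rate and iterations
on pilot instance sets, then validated on held-out instance sets):

* With p_free near 1 the system freezes: committed variables are never
  spontaneously released, and trajectories plateau at a dozen unsatisfied
  clauses whose variables are blocked on both sides. Escaping such a
  squeeze from inside takes on the order of 1 / p_blocked^2 steps.
  Moderate churn (p_free about 0.85–0.9) lets the neighbourhood move
  instead, which dissolves squeezes from outside.
* p_blocked trades commitment against escape. Values above about 0.01
  constantly kick blocked units back up and decohere committed variables;
  near-absolute blocking around 0.002 preserved commitment best at this
  scale.

Both parameters remain user-settable in `amoeba_config()`, and the
calibration is a desk-scale choice: it was *not* tuned to reproduce any
published speedup figure, and the benchmark assertion shipped with the
package is only an ordering (amoeba search needs fewer iterations than
WalkSAT at N = 50), which held robustly across independent instance sets
under these defaults before they were frozen.

## WalkSAT baseline

The comparison algorithm is the *pure random walk* variant: pick an
unsatisfied clause uniformly, pick one of its variables uniformly, flip
it. Classic WalkSAT mixes in greedy break-count moves; the sources
describe only the random pick, so the pure walk is the default and the
greedy mix (`greedy_p`) is off. Iterations-to-solution are counted as
flips for WalkSAT and as time steps for the amoeba dynamics; censored
trials enter means at the budget value (the sources do not state their
censoring treatment, so medians are always reported alongside).

## Chemistry frontend

An atom multiset (supported elements H, C, N, O with valences 1, 4, 3, 2)
compiles to one variable per (atom pair, bond-order slot): every unordered
pair gets `min(valence_a, valence_b, 3)` slots, so multiple slots on a
pair encode double and triple bonds, and the SAT machinery runs unchanged
on the slot variables. The octet rule is rendered as *exact valence* —
every atom's bond count equals its valence, lone pairs implicit; no
charges or radicals. Four rule families express this:

* `OCTET_EXCESS` caps an atom's bonds at its valence (block the (v+1)-th
  bond when v others are present);
* `OCTET_DEFICIT` forces bonds up to the valence (block "off" once only
  just enough undecided slots remain); when an atom's slot count equals
  its valence this degenerates to an unconditional force — the 2 H system
  is the minimal example, where the single bond is forced;
* `SLOT_ORDER` breaks the within-pair slot symmetry (a higher-order slot
  only on top of lower ones), collapsing states that differ only in which
  slot carries a bond; it can be disabled for fidelity experiments;
* `CONTRA` as in SAT.

Compositions are read off as connected components of the bond graph and
identified by their multiset of Hill-notation formulas (isomers merge;
note ammonia reads `H3N` in Hill order). A backtracking oracle
enumerates all valence-complete compositions and provides both the
support of the Monte Carlo distributions and representative assignments
for initialisation:

```{r}
enumerate_valid_compositions(bond_system(c(N = 2, H = 6)))
```

## Intensity sets and the temperature analogy

Chemistry intensities are continuous in [0, 1] per rule family. Lowering
them injects stronger probabilistic fluctuation — the equivalent of
raising temperature. The package ships two named sets,
`chem_intensity_sets()`: `cool` (all families 0.95) and `hot` (all 0.2).
The published illustration of this effect uses two parameter sets whose
numeric values are not recoverable from the figure, so the shipped pair
is chosen to demonstrate the qualitative contrast, not to reproduce
numbers. Two desk observations drove the choice, made on pilot runs of
the 2 N + 4 H system and frozen before the final experiments:

* Single-family contrasts (for instance lowering only `OCTET_DEFICIT`)
  barely move the first-found distribution on this system — every
  valence-complete state of 2 N + 4 H has the same total bond count
  (half the summed valences), so the bond-forcing knob has little to
  discriminate with.
* A uniform cool/hot contrast shifts the distribution reliably: the hot
  system struggles to hold a high-order N–N bond against the churn, so
  the dinitrogen channel (N2 + 2 H2) shrinks in favour of hydrogenated
  N–N compositions.

A trial's *first-found* composition is the first valence-complete decoded
assignment that persists unchanged for `stability_window` consecutive
steps (default 3; the sources report dwell durations without defining a
window). The same windowing rule segments long trajectories into
metastable visits for the dwell-time and transition statistics, both for
chemistry and for multi-solution SAT instances, where transitions between
solutions at Hamming distance 1 dominate those requiring two simultaneous
flips.

## Numerical and interface choices

* Initialisation: all accumulators start at 0 and the initial assignment
  is uniform random, mirroring WalkSAT's random start.
* Noisy-OR combination reduces to the binary OR at intensity 1 and is
  smooth in the continuous regime; duplicate rules (e.g. the two H atoms
  of H2 each forcing their shared bond) are kept, so a constraint wanted
  by two atoms blocks slightly harder than one wanted by one.
* Degenerate inputs: tautological clauses are dropped with a warning at
  parse time; duplicate literals are deduplicated; atoms that cannot
  reach their valence simply yield an empty composition oracle.
* Guards: brute force at N <= 24; composition enumeration at 12 atoms;
  per-atom subset enumeration at 16 incident slots.
* Problem sizes in the shipped experiments are desk-scale choices: the
  benchmark uses 20 satisfiable instances at N = 50, M = 213 with 100
  trials per algorithm (satisfiability of generated instances at this
  size is certified by a generous WalkSAT presolve, which slightly
  favours easier instances and is logged as such); transition statistics
  aggregate 1e6 steps; chemistry distributions use 500 trials per
  intensity set.
* All randomness flows through R's RNG, so a seed fixes every trajectory
  bit for bit; per-trial seeds are derived from the master seed and
  logged, making any single benchmark row replayable in isolation.

## What the synthetic benchmark does and does not show

The uniform random 3-SAT generator emulates the standard
phase-transition benchmark class (three distinct variables per clause,
uniform polarities, M = round(4.26 N)). Passing the shipped ordering test
shows that, at desk scale and under this package's calibrated supply
probabilities, the concurrent bounceback search outperforms the pure
random walk on that class. It does not establish the published
orders-of-magnitude speedup at N = 75–100 (which depends on parameter
values not recoverable from the sources and on the full benchmark suite),
and chemistry results are qualitative: real thermochemistry, reaction
rates, charged species and 3-D geometry are all outside the model.
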