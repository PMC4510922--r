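# amoebacsp

Amoeba-inspired stochastic search for constraint satisfaction, with a SAT
solver frontend and a chemistry frontend that explores metastable
molecules under octet-rule constraints.

A single-celled amoeboid organism searches its environment by
concurrently extending and retracting pseudopod-like branches under
inhibitory feedback. This package implements that search principle as a
generic constraint-satisfaction engine: an N-variable problem becomes a
coupled system of 2N units, one per (variable, value) hypothesis. Each
unit carries a saturating accumulator X ∈ {−1, 0, 1} driven by stochastic
resource supply, and constraints compile into *bounceback rules* — when
the units asserting a constraint-violating pattern are fully activated,
supply to the unit that would complete the violation is suppressed with a
per-rule-family intensity σ ∈ [0, 1]. Signals on a shared target combine
by noisy-OR, s = 1 − ∏(1 − σ), and supply occurs with probability
p(s) = (1 − s)·p_free + s·p_blocked. The decoded assignment, stability
criterion, metastable dwell times and solution-to-solution transition
statistics come with the engine; two frontends map problems onto it:

* **SAT** — DIMACS CNF in, clause-to-bounceback compilation, brute-force
  oracles, a uniform random 3-SAT generator at the phase-transition ratio
  M = round(4.26·N), and a pure random-walk WalkSAT baseline for
  iteration-count benchmarking.
* **Chemistry** — an atom multiset (H, C, N, O) compiles into bond-slot
  variables (one per atom pair and bond order, so double/triple bonds are
  slots) with octet-rule bounceback families; runs explore
  valence-complete molecular compositions, their first-found
  distributions under different intensity sets, and transition
  statistics between metastable molecules.

## Worked example

The bundled 4-variable, 9-clause instance has exactly three solutions:

```r
library(amoebacsp)
f <- amoeba_demo_formula()
brute_force_solutions(f)
#>      [,1] [,2] [,3] [,4]
#> [1,]    0    1    1    0
#> [2,]    1    1    1    0
#> [3,]    1    1    1    1

res <- amoeba_sat(f, amoeba_config(max_steps = 50000, seed = 42))
res$steps                      # 0-based step of the first satisfying decode
#> [1] 10
assignment_string(res$assignment)
#> [1] "1110"
```

Left running past the first solution, the dynamics visit all three
solutions and transition between them; moves requiring a single bit flip
dominate those requiring two simultaneous flips:

```r
ts <- transition_analysis(f, amoeba_config(max_steps = 1e5), seeds = 1:10)
ts$counts
#>      0110 1110 1111
#> 0110  191 3093  300
#> 1110 3096  272 3225
#> 1111  296 3230  374
```

(1111 → 1110, one flip: 3230 departures; 1111 → 0110, two flips: 296.)

On the chemistry side, two nitrogens and six hydrogens yield 30 bond
slots and exactly four valence-complete compositions, including the
dinitrogen table (N₂ + 3 H₂) and the ammonia table (2 NH₃ — `H3N` in
Hill notation):

```r
sys <- bond_system(c(N = 2, H = 6))
enumerate_valid_compositions(sys)
#> valid compositions (4):
#>   2xH2 + H2N2
#>   2xH3N
#>   3xH2 + N2
#>   H2 + H4N2
```

Monte Carlo exploration of 2 N + 4 H starting from {N₂, 2 H₂} gives the
distribution of first-found metastable compositions; the shipped `cool`
and `hot` intensity sets shift it measurably (lowering intensities plays
the role of raising temperature):

```r
run_chem(bond_system(c(N = 2, H = 4)), chem_intensity_sets()$cool,
         amoeba_config(max_steps = 20000, seed = 1),
         init = c(H2 = 2, N2 = 1), trials = 500)
#> first-found composition distribution over 500 trials:
#>   2xH2 + N2              102  (0.204)
#>   H2 + H2N2              213  (0.426)
#>   H4N2                   185  (0.370)
#>   (censored)               0  (0.000)
```

## Command line

A thin Rscript wrapper over the same functions lives at
`inst/cli/amoebacsp` (subcommands `sat-solve`, `chem-run`, `benchmark`,
`transitions`; YAML config via `--config`, every run writes a replayable
manifest):

```sh
Rscript inst/cli/amoebacsp sat-solve f.cnf --seed 42
Rscript inst/cli/amoebacsp chem-run "N:2,H:6" --trials 500
Rscript inst/cli/amoebacsp benchmark --n 50 --instances 20 --trials 100
```

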