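---
title: "Models and methods behind patrisim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind patrisim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patrisim)
```

`patrisim` implements two complementary models of how intergroup competition
among patrilineal kin groups can erase Y-chromosome haplogroup diversity
while the male census size stays constant: a stochastic discrete-time grid
model and a deterministic Lotka–Volterra competition model with a shared
female resource. This vignette is the package's account of both models, the
parameter choices, and the numerical conventions. It deliberately states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## The grid model

A population of `n_total` males is partitioned into `n_groups` cultural
groups (rows) and classified into at most `n_haplogroups` haplogroups
(columns); cell `(c, h)` counts the men of group `c` carrying haplogroup
`h`. One generation applies five operators in a fixed order: killing,
mutation, viability cull, regeneration, fission. The total population is
restored to `n_total` at every regeneration, so any loss of diversity the
model produces cannot be attributed to a demographic crash, extreme sex
ratios, or polygyny — those are all held out of the model by construction.

### Initial conditions

The two starting conditions differ only in the *within-group* association
between culture and lineage; their row and column marginals are identical,
which `summarize_state()` verifies directly in the tests:

* **PT (patrilineal):** group `j` holds all of its `S0 = n_total/n_groups`
  men in haplogroup `j`. Requires `n_haplogroups >= n_groups`.
* **NPT (non-patrilineal):** every group spreads its `S0` men as evenly as
  possible over haplogroups `1..n_groups`, remainder to the lowest column
  indices. A literal "equal frequencies over all columns" is impossible when
  `S0 < n_haplogroups`, so only the first `n_groups` columns are occupied at
  generation 0 — exactly the columns PT occupies, keeping the PT/NPT
  comparison a pure contrast of within-group correlation.

### The killing step

Group `c` of size `N_c` loses members at proportion
`p_c = min(1, D * S0 / N_c)`; each cell's deaths are drawn
`Poisson(p_c * n_ch)` truncated at the cell count. Two properties motivated
this parameterisation:

* the *expected head count* lost per group is constant in group size
  (`p_c N_c = D S0` until the cap binds), so the expected *proportion*
  killed rises as a group shrinks — small groups lose intergroup conflict
  disproportionately;
* a group at its initial size `S0` declines by exactly `D` in expectation,
  which is how the death-rate parameter is defined (the acceptance suite
  checks the calibration over 1,000 replicate killing steps, to within three
  standard errors).

### Mutation

Within each group, `floor(mu * n)` carriers of the group's major haplogroup
(largest cell in the row; ties go to the lowest column) switch haplogroup
while staying in their group. Destinations prefer globally empty columns —
each such mutation founds a new clade — falling back to a uniform draw over
the other columns only when no empty column remains. The deterministic
`floor` means a cell needs at least `1/mu` members before mutation operates
at all; with the default rate, cells below 1,000 never mutate. That stall is
an intended property of the discretisation: once haplogroup–group cells are
small, the haplogroup count can only fall.

The default `mutation_rate = 0.001` per individual per generation is a
haplogroup-*defining* mutation rate — the rate at which mutations found
clades later recognised as haplogroups — and is therefore set orders of
magnitude below per-site or haplotype mutation rates. It is exposed in the
configuration rather than hard-coded because only its order of magnitude is
constrained.

### Viability cull

A group whose size drops strictly below `extinction_threshold` (default 20,
a floor below which a "tribe" is not a viable social unit) loses all members
under the default `extirpation` rule. The alternative `fusion` rule instead
adds the row into the nearest row of viable size — ties broken toward the
row above, a fixed convention chosen for reproducibility — falling back to
extirpation when no viable row exists. The boundary is strict: a group of
exactly 20 survives.

### Regeneration

Each cell's target is `n_ch * w_c * n_total / sum(n * w)`, where `w_c` is
the group's fitness multiplier (all 1 unless cultural selection is on).
Integer counts are assigned by largest-remainder rounding with a
lexicographic `(row, column)` tie-break: the total is exactly `n_total`
every generation, the allocation is deterministic given the pre-step state,
and empty cells stay empty — reproduction never resurrects a lost
haplogroup or group.

With cultural selection on, each group independently draws fitness `1 + s`
(default `s = 0.1`) with probability 1/2 at initialisation, and fission
children inherit the parent's fitness. The model statement requires only
*that* a fitness differential exists, not its values; a two-point
distribution is the simplest choice that creates one, and `s` is exposed in
the configuration.

### Fission

Empty rows are refilled in increasing index order: the largest group (ties
to the lowest row) splits, `floor(size/2)` members drawn without replacement
across its cells (multivariate hypergeometric) forming the new group. The
split only happens while the largest group has at least twice the viability
threshold — otherwise fission would create a group the very next cull would
destroy — and once that guard fails, the remaining rows stay empty. The
guard is why the number of occupied groups can decline over a run rather
than being pinned at `n_groups`. A monochromatic parent necessarily yields a
monochromatic child, preserving the PT purity invariant.

## Summaries and ensembles

Four quantities are recorded per generation, plus the total: occupied-group
and present-haplogroup counts, and the Gini–Simpson diversity
`1 - sum(p_i^2)` of the group-size and haplogroup-size marginals. The model
statement tracks "diversity" without naming an index; Gini–Simpson was
chosen because it is bounded in `[0, 1)` like the plotted trajectories, has
the clean interpretation of a heterozygosity (probability two random men
differ in class), and attains `1 - 1/k` exactly at a uniform distribution
over `k` classes — giving the reference configurations a closed-form initial
value of 0.99.

`run_ensemble()` spawns one sub-seed per replicate from the master seed, so
an ensemble is reproducible from a single integer. Replicates in which the
whole population dies are excluded from the mean/SD aggregation and counted
(`n_dead`) rather than zero-filled, which would drag every quantity toward
zero and conflate "no data" with "no diversity". Bands are mean ± 2 SD
per generation.

### What the simulations emulate — and what they do not

The generator reproduces the study conditions: initial group size 100,
sweep over total sizes 10,000/20,000/30,000 (so 100–300 groups, haplogroup
columns at 5× the group count), death rates 0.15/0.25/0.50, 60 generations
(≈1.5 millennia), viability floor 20. The package's reference configuration
(`reference_config()`) uses 100 groups × 100 men and 500 possible
haplogroups, with death rate 0.25 — the middle of the sweep — as its
default. Ensemble tests use 20 replicates and the acceptance script 20,
sizes at which the PT/NPT separation is many standard deviations wide;
exploratory figures use 100.

Real Y-chromosome data differ in ways the grid deliberately ignores:
mutation acts on haplotypes, not haplogroups (a "haplogroup mutation" is a
modelling construct for clade-founding mutations); females are implicit;
the census size never fluctuates; and groups interact globally rather than
spatially. Passing tests therefore show that *patrilineal correlation plus
group-level extinction* is sufficient to generate bottleneck-like diversity
loss under constant census size — not that these parameter values describe
any particular ancient population.

## The Lotka–Volterra model

Two male subpopulations share one female population that grows logistically
and is unaffected by male dynamics:

$$
\begin{aligned}
dY_1/dt &= Y_1\,(r_1 X - c_{11} Y_1 - c_{12} Y_2)\\
dY_2/dt &= Y_2\,(r_2 X - c_{21} Y_1 - c_{22} Y_2)\\
dX/dt   &= a X (1 - X/K)
\end{aligned}
$$

`X` decouples and follows the logistic closed form, which the test suite
uses as an exact oracle. When `min(c12, c21) > max(c11, c22)` — between-group
competition strictly dominating within-group competition — the two male
lineages cannot coexist on the single shared resource and one is driven to
extinction from almost every starting point; the exception is the symmetric
separatrix, a measure-zero set. The package establishes the outcome by
integration rather than by the analytic basin boundary, and the property
test draws 100 random parameter sets satisfying the condition (with starts
kept off the near-symmetric diagonal) and requires at least 95 single
extinctions.

### Numerical conventions

* Integration uses `deSolve`'s adaptive `lsoda` with `rtol = 1e-9`,
  `atol = 1e-12`; an independent fixed-step Euler oracle at `dt = 1e-4`
  (kept in the test helpers, deliberately outside the package) must agree
  within `1e-3` sup-norm on the worked example.
* State components are clamped at zero: `Y_i = 0` is absorbing in the exact
  system, so negative undershoots are integrator artifacts, not dynamics.
* "Extinct" means: below `eps` (default `1e-6` times the larger initial
  male population) and never above it again within the trajectory.
  "Coexistence" additionally requires the end-of-trajectory derivatives to
  be settled below `1e-8` in absolute value. Anything else is "undecided".
  These thresholds are numerical stand-ins for an asymptotic statement; they
  are conventions, not fitted values.
* `interior_equilibrium()` solves the 2×2 linear system at `X = K` and
  reports an equilibrium only when both components are strictly positive.

## Degenerate inputs and failure modes

* A configuration whose total is not divisible by the group count, or a PT
  start with fewer haplogroup columns than groups, is rejected at
  construction.
* A fully extinct grid raises a condition of class `patrisim_dead` naming
  the generation; `run_ensemble()` catches it per replicate.
* `gini_simpson()` and `summarize_state()` refuse all-zero inputs rather
  than returning a conventional value.
* Config files with unknown keys are rejected outright, so a misspelled
  parameter cannot silently fall back to its default.

## Known limitations

* Haplogroup-level mutation is a coarse proxy for haplotype evolution; the
  model cannot produce coalescent trees or skyline estimates on simulated
  data.
* The fusion rule is the only spatial structure in the model; there is no
  stepping-stone geography.
* Cultural selection's fitness distribution (two-point, probability 1/2) is
  one simple choice among many the model statement would admit.
* The Lotka–Volterra component is deterministic; stochastic variants and
  more than two male lineages are out of scope.
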