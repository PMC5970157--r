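# patrisim

Forward-time simulation of competition between patrilineal kin groups and its
effect on Y-chromosome haplogroup diversity.

## The problem

Around 5000–7000 years BP, inferred male effective population size collapsed
relative to female — a Y-chromosome "bottleneck" — without clear evidence of
an actual demographic crash. One proposed explanation is *cultural
hitchhiking*: if society is organised into patrilineal kin groups, every man
in a group carries the same Y lineage, so when intergroup competition wipes
out a group it wipes out a whole haplogroup. Y diversity can then crater even
while the total number of men stays constant.

`patrisim` is for population geneticists and students of cultural evolution
who want a tested, reproducible implementation of the two models behind this
argument:

1. **A discrete-time grid model.** A constant population of `N` males is laid
   out on a `|C| × |H|` grid of cultural groups (rows) by haplogroups
   (columns). Each generation applies, in order:
   * **killing** — group `c` of size `N_c` loses each cell's members with
     truncated-Poisson deaths at proportion `p_c = min(1, D·S0/N_c)`, so the
     expected decline of a group at its initial size `S0` is exactly the
     death rate `D`, and smaller groups suffer proportionally more;
   * **mutation** — `⌊μ·n⌋` carriers of each group's major haplogroup mutate
     to other haplogroups (new, globally empty columns first), staying in
     their group;
   * **viability cull** — groups below 20 members are extirpated (or fused
     into the nearest viable group);
   * **regeneration** — the grid is scaled back to exactly `N` by
     largest-remainder proportional allocation, optionally weighted by
     cultural-selection fitness;
   * **fission** — the largest group splits in half to refill vacated rows.

   Under a *patrilineal* (PT) start each group is fixed for its own private
   haplogroup; under a *non-patrilineal* (NPT) start every group mirrors the
   population-wide haplogroup distribution. The marginals are identical at
   generation 0 — the two conditions differ only in the within-group
   correlation between culture and lineage.

2. **A modified Lotka–Volterra competition model.** Two male subpopulations
   `Y1`, `Y2` share one logistic female resource `X`:

   ```
   dY1/dt = Y1 (r1 X − c11 Y1 − c12 Y2)
   dY2/dt = Y2 (r2 X − c21 Y1 − c22 Y2)
   dX/dt  = a X (1 − X/K)
   ```

   When cross-group competition strictly dominates within-group competition,
   `min(c12, c21) > max(c11, c22)`, one male lineage is (almost always)
   driven to extinction — competitive exclusion with a single shared
   resource.

Diversity is tracked with the Gini–Simpson index `1 − Σ pᵢ²` on the group and
haplogroup marginals.

## Worked example

```r
library(patrisim)

pt  <- run_simulation(reference_config(patrilineal = TRUE,  seed = 7))
npt <- run_simulation(reference_config(patrilineal = FALSE, seed = 7))
pt
#> <sim_trajectory> 60 generations (PT start)
#>   final: 10000 males, 100 groups, 16 haplogroups, haplogroup diversity 0.904
npt
#> <sim_trajectory> 60 generations (NPT start)
#>   final: 10000 males, 100 groups, 89 haplogroups, haplogroup diversity 0.982
```

Both runs start from identical marginals: 10,000 men, 100 groups of 100, 100
haplogroups present (diversity 0.99). After 60 generations of identical
competition dynamics, the patrilineal population has lost 84 of its 100
haplogroups and its haplogroup diversity has fallen to 0.90, while the
non-patrilineal population still carries 89 haplogroups at diversity 0.98 —
a bottleneck signal produced with zero change in male census size.

Ensembles and plots:

```r
ens <- run_ensemble(reference_config(patrilineal = TRUE), n_runs = 100)
tidy(ens)       # generation × quantity long table: mean, sd, mean ± 2 SD
autoplot(ens)   # trajectory panels with 2-SD bands
```

The Lotka–Volterra side:

```r
p <- lv_params(r1 = 1, r2 = 1, c11 = 1, c12 = 2, c21 = 2, c22 = 1, a = 1, K = 1)
check_exclusion_condition(p)
#> [1] TRUE
traj <- integrate_lv(p, c(X = 0.5, Y1 = 0.6, Y2 = 0.4), t_end = 200)
classify_outcome(traj)
#> <lv_outcome> Y2_extinct (t = 19)
```

The initially smaller male lineage is excluded; its extinction time is
reported on the model's time scale.

A command-line front end wraps the same functions
(`system.file("exec", "patrisim", package = "patrisim")`):

```sh
patrisim simulate --config cfg.yaml --out out/        # one run
patrisim ensemble --config cfg.yaml --out out/ --runs 100
patrisim sweep    --out out/ --runs 100               # full 18-config sweep
patrisim lv       --out out/ --c12 2 --c21 2
```

Every invocation writes a JSON run manifest (config, seeds, outputs) from
which its files can be reproduced bit-for-bit.

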