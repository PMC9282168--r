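# placetheta

An R package that simulates and analyzes a feedforward
entorhinal-to-hippocampus learning model in which modelled hippocampal
cells acquire **place fields** and **theta phase precession** purely
through synaptic plasticity, by non-negative sparse coding of entorhinal
input.

## The scientific problem

Hippocampal place cells fire at a single location of a small environment,
and their spikes drift from late to early phases of the theta rhythm as
the animal crosses the place field (phase precession).  Upstream, medial
entorhinal (MEC) grid cells show the same two properties, but on a
hexagonal lattice of firing fields.  This package implements a learning
account of the link: a population of hippocampal units with
locally-competitive-algorithm (LCA) dynamics

```
tau du/dt = -u + A'I - (A'A - 1) s,      s = max(u - beta, 0)
Delta A   = eta (I - A s) s',            A >= 0, unit-norm columns
```

learns its feedforward dictionary `A` online while a virtual rat forages
in a 1 m x 1 m arena.  The input `I` comes from a generative population of
**spatiotemporal grid cells** — firing fields of radius `R = 0.32 lambda`
on hexagonal lattices (four modules, spacings 38.8–98.4 cm), modulated in
time by `exp(k_phi (cos(2 pi F t - phi(r)) - 1))` with `F = 10` Hz, where
the phase `phi(r)` falls linearly with the projected distance along the
current running direction (pdcd) across each field — plus, in scenario 2,
**weakly spatial cells** (smoothed-noise maps scaled to `[0, 0.1]`).

Three scenarios reproduce the model's main results:

1. grid input only — units learn single place fields *and* inherit
   near-perfect phase precession;
2. grid + weakly spatial input — same outcome with mixed input;
3. grid rows of the learnt dictionary severed, learning off — place
   fields survive on weakly spatial input alone (slightly enlarged),
   while the temporal code is lost with its source.

After learning, the package recovers occupancy-averaged rate maps
(40 x 40 bins), fits spatial (`alpha_c exp(-ln5 |r - r_c|^2 / R^2)`) and
spatiotemporal (`alpha exp(k_phi (cos(2 pi F t - phi) - 1))`) response
models by Levenberg–Marquardt least squares, selects place cells (center
inside the arena, radius > 5 cm, fitting error < 40%), and measures
precession as the Pearson correlation between fitted phase and
normalized pdcd along a curved crossing of the fitted field.

## Worked example

A scaled scenario-1 run (64 hippocampal cells, 400 grid cells, 600 s of
training — a few minutes of CPU):

```r
library(placetheta)
cfg  <- scenario_config(1, n_hippocampal = 64, n_grid = 400,
                        train_duration = 600, test_duration = 400,
                        master_seed = 42)
rep1 <- run_scenario(cfg)
print(rep1)
#> Scenario 1 report
#>   48 / 64 cells pass the place-cell criteria
#>   29 place fields lie entirely inside the arena
#>   mean fitted radius over place cells: 10.29 cm
```

Three quarters of the units became place cells with ~10 cm fields.  Probe
the temporal code of one of them:

```r
k  <- rep1$fully_inside[1]
f  <- rep1$fits[rep1$fits$cell == k, ]
p  <- measure_precession(rep1$model, rep1$population, k, f, seed = 99 + k)
print(p)
#> Phase precession summary: 32 in-field samples
#>   entry phase 347.8 deg, exit phase 73.4 deg
#>   phase vs normalized pdcd correlation: -0.8939
```

The cell enters its field firing at a late theta phase (~348 deg), exits
at an early phase (~73 deg), and the fitted phase falls monotonically
with the normalized projected distance — theta phase precession inherited
entirely through learning (across the population, correlations cluster
below -0.99).  Full-scale runs use the defaults
(`scenario_config(1)`: 900 grid cells, 100 hippocampal cells, 3600 s
training) and take on the order of an hour.

A thin command-line front end is available at
`inst/cli/placetheta-cli.R` (`simulate-trajectory`, `run-scenario`).

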