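# rescuesim

Agent-based simulation of a three-dimensional society of normal and tumor
cells, built to study a question in computational oncology: what minimal
*cooperative* behaviors — "citizenship properties" — must cells retain for a
tissue to selectively eradicate a growing tumor through inter-cellular
signaling alone?

Cells live on a bounded lattice (one cell per site) and follow stochastic
life protocols: proliferation under contact inhibition (normal cells divide
only into free neighboring sites, tumor cells may push into the radius-2
shell), heritable heterogeneous rates (tumor proliferation `p_t ∈ [0.3, 0.9]`
per step against normal `p_n ∈ [0.05, 0.15]`, `[0.03, 0.09]` or
`[0.015, 0.045]` for proliferation ratios `p_t/p_n` of 6, 10, 20), intrinsic
apoptosis, generation potential, and mutation with a repair-first ordering.
Two rescue protocols act through per-cell signal accumulators with
two-threshold responses:

- **please die** — a normal cell violated by an adjacent tumor deposits a
  decaying signal `s·(1 − d/(r+1))` on every cell within radius `r`; tumor
  cells crossing the high threshold apoptose, and primed normal cells emit
  early when a tumor approaches;
- **I'm dying** — a cell killed by a rescue protocol reports its death;
  reports carry apoptosis into the tumor interior (a chain advancing one
  shell per step) and accelerate normal repopulation through the low
  threshold.

Tumor resistance is modeled deterministically (a minimum count of distinct
apoptotic requests) and stochastically (each received signal ignored with
probability `q`; each death report withheld with probability `f`).  A run is
a *success* when every tumor cell dies without irreversibly wiping out the
healthy tissue (final normal count ≥ 50% of its count at rescue activation).
The experiment layer runs seeded replicates over protocol-parameter grids,
resistance levels and delayed-activation volumes, with Wilson-interval
success-rate summaries.  See `vignettes/rescue-protocols.Rmd` for the full
model description and design rationale.

## Worked example

One full experiment — grow a 20×20×20 membrane from a single founder, plant
one tumor cell at confluence, battle with both protocols active:

```r
library(rescuesim)
cfg <- sim_config()          # ratio 6, signal set 2, default thresholds
r   <- sim_run(cfg, seed = 73, record = TRUE)
r
#> <sim_run seed 73  outcome success  battle steps 1  normal 0.996  tumor 0.000>
```

The planted tumor sits among 26 violated normal cells; their please-die
deposits cross the unit tumor threshold in the first step, so the tumor is
removed before it can divide and 99.6% of the membrane remains normal.
Resistance makes the battle longer but rarely changes its outcome:

```r
run_replicates(sim_config(ignore_prob = 0.68), 30, master_seed = 1)$success_rate
#> [1] 1
```

Delayed activation is the harder regime — the tumor grows freely until it
holds a fraction `V` of the system:

```r
sim_run(sim_config(activation_volume_frac = 0.6), seed = 4)
#> <sim_run seed 4  outcome success  battle steps 58  normal 0.203  tumor 0.000>
```

Here 4800 tumor cells are eradicated in 58 steps and the tissue regrows to
half of its at-activation count (1624 of baseline 3200 normals).  A
command-line driver wraps the same functions
(`inst/cli/rescuesim run --config c.yaml --seed 7 --trace`, subcommands
`grow`, `run`, `sweep`, `snapshot`).

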