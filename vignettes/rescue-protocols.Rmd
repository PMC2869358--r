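---
title: "Cooperative apoptosis rescue protocols on a 3-D cell lattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cooperative apoptosis rescue protocols on a 3-D cell lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rescuesim)
```

## The model

`rescuesim` simulates a society of cells on a bounded 3-D lattice (a
"membrane" of `nx * ny * nz` sites with hard walls, at most one cell per
site).  Cells carry a phenotype, *normal* or *tumor*, and per-cell stochastic
parameters: a per-step proliferation probability, a per-step intrinsic death
probability, a generation potential (remaining divisions), and four
protocol-integrity flags (repair, apoptosis, proliferation-suppression,
distance regulation).  Time advances in synchronous steps; within each step
the phases run in a fixed order (intrinsic deaths, signal emissions, signal
accumulation, threshold responses, simultaneous removal of the dead,
divisions in randomized order).  All randomness is drawn from R's RNG, so a
`(configuration, seed)` pair determines a trajectory bit for bit.

**Life protocols.**  A normal cell divides only into a free site of its
26-neighborhood (contact inhibition); a tumor cell whose neighborhood is
full may fall back to a free site on the radius-2 shell, the local
"pressure" with which tumors violate spatial regulation.  Normal cells with
an adjacent tumor also divide at a reduced rate (suppression factor 0.5 by
default), which widens the effective proliferation gap.  Daughters inherit
the parent's probabilities with a symmetric multiplicative skew (10% by
default), clipped into the population range, and one unit less generation
potential (50 divisions by default for normal lineages, unlimited for
tumors).  Intrinsic apoptosis is a per-step Bernoulli draw, with an
optional deterministic senescence death once the generation potential is
exhausted.  Tumorigenesis runs at the division checkpoint: each intact
guard protocol can be lost with a configurable probability, but while
repair is intact it restores any other loss from the same checkpoint, so
repair must fall first; a cell that has lost all four guards is a tumor
cell and can never revert.  Spontaneous mutation is off by default -- the
sweep experiments instead *plant* one tumor cell (sampled from the tumor
ranges) in place of one resident cell at confluence, which starts every
experiment from a single cancer cell at a known time.

**Population presets.**  The proliferation ratio labels the quotient of
tumor and normal proliferation ranges.  Tumor cells always draw from
[0.3, 0.9] per step with intrinsic death in [0.0001, 0.0002]; normal cells
draw from [0.05, 0.15] (ratio 6), [0.03, 0.09] (ratio 10) or
[0.015, 0.045] (ratio 20), with death in [0.0024, 0.0048].  The ranges
themselves encode the population heterogeneity: the death range spans a
factor of 2 and the normal proliferation ranges a factor of 3.

## The rescue protocols

Two inter-cellular signals implement the cooperative "citizenship"
machinery.  Signals exist only on cells (no free-space field, no diffusion
PDE): an emission deposits, at every occupied site within the signal
radius, the decayed strength `s * (1 - d / (r + 1))` at Chebyshev distance
`d` (exponential decay and Euclidean distances are config options).  Each
receiving cell folds deposits into per-cell accumulators with retention
`rho` per step (`acc' = rho * acc + deposits`; default `rho = 1`, a pure
sum over time, the literal reading of "total strength received over
time").

* **Please die.**  A normal cell that is spatially violated (tumor within
  radius 1) emits the please-die signal.  A cell whose apoptotic
  accumulator has reached the *low* please-die threshold is *primed* and
  emits already when a tumor comes within radius 2 -- it emits sooner,
  which is what resists tumor re-growth near a former battle site.
* **I'm dying.**  A cell killed *by a rescue protocol* reports its death
  over the phenotype-specific radius.  Normal cells always report; a dying
  tumor cell withholds its report with probability `f` (stochastic
  resistance on the emission side).  Intrinsic (homeostatic) deaths do not
  report by default -- only protocol deaths do -- which keeps background
  turnover from integrating into false apoptosis under `rho = 1`; the
  `emit_on_intrinsic_death` switch restores fully symmetric reporting.

Responses are two-threshold.  A tumor cell apoptoses once its apoptotic
accumulator reaches the tumor high threshold *and* it has received at least
`det_counts["tumor"]` distinct above-half-strength requests (deterministic
resistance; the per-deposit ignore probability `q` is applied at deposit
time, so an ignored signal neither accumulates nor counts).  A normal cell
apoptoses at its own high threshold; below it, death reports reaching the
low repopulation threshold temporarily double its division rate (2x for 5
steps, re-triggered while the threshold holds), and please-die exposure
reaching the low please-die threshold primes early emission.  Apoptosis
marks are applied simultaneously, and a protocol-killed cell's death report
is delivered in the next step's accumulation, so a death chain advances
about one shell per step into a tumor cluster -- the mechanism that carries
eradication from the violated periphery into the interior.  Deposits are
addressed to cell identities, not sites, so a daughter born into a vacated
site never inherits its predecessor's signal.

### Default thresholds and why they are asymmetric

The high thresholds default to 1 signal unit for tumor cells and 4 for
normal cells, with both low thresholds at 0.5.  The asymmetry is a design
choice with a mechanistic reason.  Because tumor growth at confluence is
limited to sites vacated by dying neighbors (with the radius-2 fallback),
a tumor left to grow becomes interdigitated with the tissue rather than a
clean sphere; once it occupies a third of the system, nearly every normal
cell is violated and emitting.  With a symmetric unit threshold the
resulting friendly-fire exceeds a normal cell's threshold within a single
step and the tissue annihilates itself.  Normal cells retaining a several-
fold higher apoptotic threshold -- the same direction and range as the
threshold pairs the deterministic-resistance experiments explore (1/1 up
to 6/16, the normal threshold never below the tumor's) -- lets the tissue
survive the short global flash in which the tumor is destroyed, while
still allowing collateral death where many emitters concentrate.  By
default death reports do not feed normal cells' apoptotic accumulator at
all (they drive repopulation instead): with symmetric report-induced
apoptosis, a planar front of dying normals delivers on the order of nine
simultaneous deposits to the next layer, which self-sustains a death wave
through healthy tissue at any realistic threshold.  Selectivity against
the tumor interior comes from density of simultaneously dying neighbors,
which is a tumor-cluster property; `im_dying_kills_normals` restores the
symmetric variant for experimentation.

## Runs, outcomes and experiments

A full experiment (`sim_run`) grows the membrane from a single founder to
confluence (occupancy at least `confluence_frac`, default 0.995 -- the
birth/death equilibrium keeps a handful of transient holes open in an
8000-site membrane, while a 125-site membrane still reaches exactly 125
cells; if the founder lineage stochastically dies out first, a fresh
founder is seeded from the same stream), plants one tumor cell, optionally
waits with protocols inactive until tumor occupancy reaches an activation
volume, then battles for up to `max_steps = 500` steps.

A run is a **success** when every tumor cell is dead and the normal
population holds at least `integrity_frac = 0.5` of its baseline, the
normal count *at rescue activation*.  The baseline is taken at activation
rather than at planting deliberately: when activation is delayed until the
tumor holds 60% of the system, the normal count is arithmetically at most
40% of its planting value, so a planting-time baseline would declare every
late-activation run a failure before the protocols act; the protocols
should be judged on what they preserve of the tissue they were given.
For the same reason the run does not stop the moment the tumor dies if the
tissue is still below the bar -- "irreversibly wiping out" is a statement
about the end state, so stepping continues and the tissue may repopulate
the evacuated space; the run exits early only once success is locked in
(no tumor can re-appear without back-mutation, and with no tumor present
no apoptotic signal flows).  Runs that end with live tumor cells are
timeouts; a tissue below the bar at the horizon is a collapse.

The experiment layer derives a seed for every sweep condition by hashing
its label together with the master seed, so results are independent of
sweep order, and summarizes success counts with Wilson score intervals.
`sweep_protocol_grid` crosses proliferation ratios with the five signal
presets (and optionally threshold pairs), `sweep_resistance` scans the
ignore probability `q` and emission-failure probability `f` separately,
and `sweep_activation_volume` scans delayed activation volumes.

## Numerical and scale choices

The study conditions used by the test suite and the acceptance script are
a 20 x 20 x 20 membrane (8000 sites), 30 seeded replicates per sweep
condition (40 for the resistance-margin conditions), ratio 6 with signal
preset 2 as the baseline, and immediate activation unless the activation
volume is swept.  These sizes keep a full protocol grid (450 runs) around
half a minute and the nine-volume activation sweep a few minutes on one
CPU, while leaving each condition's Wilson interval narrow enough to
distinguish majority success from failure.  Unit tests use 5--12 sites per
axis, where every relevant geometry (corners, full neighborhoods,
two-shell tumor blobs) can be constructed exactly.

Ties and degenerate inputs are handled explicitly: division candidates are
enumerated in lexicographic order and picked uniformly with one RNG draw;
a zero-proliferation configuration reaches its growth cap and is flagged
rather than looping; planting into a transient center hole falls back to
the nearest occupied site; an empty grid cannot be planted and errors.

## What the generator does and does not emulate

The synthetic study conditions reproduce the *structure* of the biological
question -- heterogeneous stochastic phenotypes, contact-inhibited growth,
a proliferating resistant tumor, noisy cooperative signaling -- not any
particular tissue's physiology.  Lattice granularity, the Chebyshev
metric, the linear decay law, and the signal-unit scale are conventions;
nothing calibrates them to physical units.  Passing tests therefore show
that the cooperative-protocol mechanism is robust *within this model
class*: they support the qualitative claims (periphery-only reach of
please-die alone, interior kill via death reports, tolerance of majority
non-compliance, a window for late activation) but say nothing quantitative
about real tumors, real signaling molecules, or clinical margins.

## Known limitations

* Tumor morphology under confluent growth is interdigitated rather than
  spheroidal, which makes delayed-activation battles global rather than
  interface-limited; the threshold asymmetry above compensates.
* With retention `rho = 1` accumulators never decay, so any cell
  persistently exposed to sub-threshold signal eventually responds;
  battles here are short enough that this only matters for deliberately
  long custom horizons.  Set `rho < 1` for leaky accumulation.
* Angiogenesis, chemotherapy, immune mechanisms and molecular identities
  of the signals are out of scope, as is any continuous-space or
  event-driven scheduling.
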