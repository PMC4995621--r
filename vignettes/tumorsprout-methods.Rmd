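---
title: "The tumorsprout model: assumptions, calibration, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The tumorsprout model: assumptions, calibration, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tumorsprout` is an agent-based model of an avascular tumor that recruits
its own blood supply. Three cell types — tumor cells, endothelial cells,
and fibroblasts — act on a bounded 3D lattice (one site = 5 µm, at most one
cell per site), coupled through four diffusing molecular fields: oxygen
(standing in for oxygen *and* nutrients), VEGF, FGF and HGF. All
behavior of the system — the necrotic core, the brush-border branching
pattern of the vasculature, the angiogenic switch, the
linear-to-exponential growth transition and the recovery turning point —
emerges from per-cell rules; nothing of it is scripted at the population
level.

This vignette records the model's assumptions, the meaning and calibration
of its parameters, and the design decisions that were genuinely open, in
the spirit of a methods supplement.

## Cell behaviors as statecharts

Each cell type runs a small hierarchical state machine, and the package
ships a generic statechart engine (`sc_machine()`, `sc_instantiate()`,
`sc_dispatch()`, `sc_tick()`) on which the three machines are declared
(`tumor_machine()`, `endothelial_machine()`, `fibroblast_machine()`). The
engine supports nested states with one initial child per composite state,
orthogonal regions, per-state tick timers, and guarded transitions.
Transition priority is fixed: the deepest enabled source wins, remaining
ties fall back to declaration order (strict mode turns such ties into
errors). Timers reset on state re-entry.

The production time-stepping loop is compiled (Rcpp) for speed and executes
the same transition rules in compiled form; the R-level machines are the
readable specification and the reference semantics. The test suite drives
single cells through both paths and asserts identical state traces
(hypoxia onset, necrosis timing, VEGF pulse schedules), which is what keeps
the two representations honest.

### Tumor cells

A tumor cell consumes `OxygenNeedPerStep` (default 1 unit/tick), pooled
nearest-first over its Moore neighborhood. A tick with a full grant resets
the oxygen-deficit counter; `HypoxiaLevel` (20) consecutive deficit ticks
make the cell hypoxic — alive, VEGF-secreting, but unable to proliferate —
and `AnoxiaLevel` (400) consecutive deficit ticks make it necrotic:
permanently inert, but left on the lattice as an obstacle (a documented
alternative would clear it; we keep it, since nothing in the biology
removes the debris on these time scales). Hypoxia is fully reversible at
any point before anoxia.

Hypoxic cells emit `VEGFSecretionAmount` (8000) every `VEGFPulsePeriod`
(10) ticks — pulsed, not continuous — and stop once the deficit passes
`VEGFSecretionDeficitLimit` (350): a cell on the brink of necrosis is
treated as too compromised to sustain synthesis. Living cells deposit
`FGFSecretionAmount` FGF every tick, the chemoattractant that later guides
CAFs.

Division is clocked: `ProliferationPeriod` (15) *fed* ticks per division,
into a uniformly random empty neighbor. Two choices here matter and are
ours: the clock only advances on ticks where the cell met its full oxygen
need (growth costs nutrients — without this gate a cell fed one tick in
twenty would proliferate at full speed and the pre-vascular growth halt
could never happen), and local HGF above `HGFThreshold` divides the period
by `HGFBoost` (2), which is how CAF support accelerates the tumor.
Movement is possible but rare: probability `BaseMotility × (1 − ECM)`, so
tumor cells only become motile where CAFs have degraded the matrix.

### Endothelial cells

Initial vessels are straight chains of quiescent endothelial cells (four
chains of `vessel_length` 12 cells in the shipped geometry). Each cell
binds (consumes) local VEGF up to `VEGFBindingCapacity` (8 units/tick)
and remembers its last `ActivationWindow` (300) per-tick amounts. A
quiescent cell whose windowed sum reaches `AngiogenicSwitchThreshold`
(100) becomes a tip — the angiogenic switch — and, delta-notch style,
permanently inhibits its 26 lattice neighbors from ever activating. The
window is deliberately long relative to `threshold / binding rate` for
vessels at the shipped 200-µm distance: activation is *integrative*, so
quartering the tumor's VEGF output roughly quadruples the time to the
switch instead of abolishing it ("low VEGF activates later"), while
vessels at 300 µm see a bounded steady window far below the threshold and
never activate. Binding also requires a pooled local availability of at
least `VEGFBindingFloor` (0.2): receptor engagement at trace
concentrations is treated as nil, which keeps the faint far-field tail
from being integrated at all.

A tip elongates by spawning a new endothelial cell into the unoccupied
neighbor with the most VEGF (the old tip becomes a stalk cell, the new
cell the tip), on average once per `SproutPeriod` (5) ticks — endothelial
proliferation is slower than the tumor's front. If the best target holds
an endothelial cell of a different vessel, the sprout fuses with it
instead — anastomosis — and stops elongating. A sprout never fuses with
its own vessel or with the vessel it branched from, which would otherwise
happen instantly at the moment of sprouting. Stalk cells that bind
`BranchThreshold` (190) within `BranchWindow` (30) ticks spawn a second
tip into a fresh daughter vessel (with parent lineage recorded), then
clear their binding window; since saturated binding over the branch
window caps at `VEGFBindingCapacity × BranchWindow = 240`, branching
demands near-maximal VEGF exposure, which in practice only the
peritumoral vessels see — the brush-border effect. Lateral inhibition
applies to branching as in tip selection generally: an inhibited stalk
does not branch, and a branch point inhibits itself and its neighbors,
which spaces sprouts and keeps the vasculature from doubling every branch
window inside the saturated peritumoral field.

Newly formed (sprout) cells die of VEGF starvation: `StarvationLimit`
(40) consecutive ticks with local availability below `EndothelialMinVEGF`
kill the cell and every newly formed cell distal to it in its vessel,
until the cell matures at `EndothelialMaturationAge` (100 ticks) into an
established vessel cell that no longer needs the signal. We test
availability rather than the amount actually bound (with the binding
floor, bound VEGF is zero wherever concentrations are trace), and we let
sprouts mature, because under the literal rules the entire neovasculature
would dismantle the moment the rescued tumor stops signalling and the
system would oscillate between rescue and collapse.

### Fibroblasts and CAFs

Fibroblasts are seeded in a shell around the tumor and consume a smaller
maintenance ration, `FibroblastOxygenNeed` (0.25 units/tick) — they are
quiescent stromal cells, not proliferating tumor tissue. A fibroblast
within `CAFRadius` (10 sites) of a living tumor cell that met its oxygen
need converts to a cancer-associated fibroblast with probability
`CAFBaseProb` per tick, irreversibly. CAFs secrete VEGF on the common
pulse schedule, scaled by `min(deficit / HypoxiaLevel, 1)` — output
proportional to their own oxygen distress — times `CAFVEGFFraction`
(0.1) of a tumor cell's pulse (stromal cells are far weaker VEGF sources;
at parity their pulses alone, emitted from the stromal shell, would
activate even 300-µm vessels), plus HGF every tick; they
degrade the ECM around themselves at `ECMDegradationRate` and move one
site per tick up the FGF gradient (never down it), which carries them to,
and into, the tumor.

## Molecular fields

Fields live on the same lattice as the cells. Diffusion is the
expectation of a random walk taking independent uniform {−1, 0, +1} steps
per axis: each site keeps 1/27 of its mass and spreads the rest over its
Moore neighborhood, with reflecting boundaries (mass that would leave
stays). The kernel is applied as three separable one-dimensional passes,
which is exact for this kernel and an order of magnitude cheaper than the
27-point gather. A Monte-Carlo walker implementation of the same walk
(`walker_occupancy()`) is kept purely as an independent oracle; the test
suite checks the kernel against 3 × 10⁵ walkers on a 9×9×9 world.

Species differ in speed and reach. Oxygen and VEGF take
`OxygenDiffusionSteps` / `VEGFDiffusionSteps` (6) kernel applications per
tick, FGF and HGF 1. Each species also decays at a first-order per-tick
rate (`OxygenDecayRate` 0.006, `VEGFDecayRate` 0.05, FGF/HGF 0.01), i.e.
it is cleared as in any reaction–diffusion tissue model. Decay is a
deliberate departure from a purely conservative field (consumption as the
only sink): in a closed reflecting box a conserved species has no steady
state — secreted VEGF eventually floods the entire lattice above any
activation threshold, and any trickle of conserved oxygen sustains
arbitrarily distant cells indefinitely. With clearance, a continuous
source has the classic exponentially attenuated profile with range
`sqrt(D/λ)` (≈ 18 sites for oxygen, ≈ 6 for VEGF), which is precisely
what makes 200 µm vessels reachable and 300 µm vessels not: over the
extra 100 µm between the near and far placements the steady VEGF level
falls by more than an order of magnitude, and the far vessels' windowed
binding stays well below the activation threshold at any secretion level
the tumor reaches.

The per-species mass ledger is exact at every tick:
`initial + deposited − consumed − decayed = remaining`, to 10⁻⁹ relative.
`field_diffuse()` itself conserves mass identically.

## The shipped scenarios

`scenario_preset()` bundles the study conditions: a 100³ world (500 µm
cube), one tumor cell at the centre, four vessel chains of 12 cells at
`InitialVesselDistance` 40 sites (200 µm), 150 fibroblasts in a 15–35-site
shell, a uniform initial oxygen background (`OxygenBackground` 1.2) and a
1200-tick horizon. `far_vessels` moves the vessels to 60 sites (300 µm)
in a widened 131×131×101 world. `no_angiogenesis` disables endothelial
activation and places the initial vessels at the world border — the
alternative placement mode — so that the static vasculature is too remote
to feed the tumor. `non_proliferating` seeds a non-cancerous, non-dividing
cell and gives it the quiescent stromal oxygen ration
(`FibroblastOxygenNeed`, 0.25): a resting normal cell's maintenance
metabolism is a fraction of a proliferating tumor cell's. The
`low_*`/`high_*` presets scale one parameter by 1/4 and 4 (1/2 and 2 for
the switch threshold, whose reachable range is bounded by
`VEGFBindingCapacity × ActivationWindow`).

The scheduling contract: per tick, all four fields diffuse and decay,
then every living agent acts once, in a freshly drawn random permutation
(fixed update orders introduce lattice drift artifacts); then metrics are
appended. A single `mt19937_64` stream seeded from the scenario seed
drives every draw, with hand-rolled bounded-integer rejection sampling so
that trajectories are bit-identical across platforms.

## Calibration

The model's quantitative behavior rests on a calibrated default parameter
set (`sim_params()`), chosen once so that the baseline run reproduces the
canonical solid-tumor trajectory: a slow, roughly linear avascular phase;
a growth halt as the local oxygen is spent; pulsed VEGF reaching the
vessels after a diffusive delay of a few hundred ticks; the angiogenic
switch; sprouts crossing the 40-site gap; then exponential, vascularized
growth with a central necrotic core — while the `far_vessels`,
`no_angiogenesis` and `non_proliferating` variants reproduce their
qualitative outcomes (no activation at 300 µm; starvation to zero without
angiogenesis; indefinite survival of a single quiescent cell). The
interlocking constraints are tight: oxygen clearance must be slow enough
for vessel oxygen to span 40 sites (the quiescent-cell case) yet fast
enough that the initial background cannot sustain the halted tumor
forever (the extinction case); VEGF clearance must pass 40 sites at
binding-relevant levels but not 60. The development levels the presets
reach — tens of thousands of living tumor cells, thousands of endothelial
cells — follow emergently and were not individually imposed.

One reading note for the brush-border analysis: over a whole 1200-tick
trajectory the raw branch-event histogram rises with distance, for a
trivial geometric reason — the packed tumor interior offers no empty site
to branch into, and the branching rim sweeps outward with the growing
tumor while the vasculature thickens. The brush-border claim ("vessels
branch more as they approach the tumor") is therefore evaluated at the
epoch the tumor first reaches its developed 16,000-cell size and over the
extratumoral bins, where the approach gradient is meaningful; there the
branch counts fall monotonically with distance.

What the synthetic scenarios do *not* emulate: real vascular perfusion
(oxygen appears at endothelial cells, not from blood flow), immune and
lymphatic components, mechanical stress, off-lattice geometry, and any
physical-unit mapping of tick or concentration (amounts are model units;
ticks are abstract). Passing tests therefore demonstrate the internal
consistency and the qualitative emergent repertoire of the model, not
quantitative agreement with any experimental tumor.

## Numerical and degenerate-input choices

- Pooled consumption takes nearest-first (own site, then face, edge,
  corner neighbors), proportionally within a distance class — deterministic
  given the field, no sampling.
- Gradient steps break ties uniformly at random; a locally flat field
  yields a uniformly random direction.
- Timers and windows are integer ticks; re-entry resets timers.
- An empty world steps to all-zero metrics; an empty radial selection is
  an empty profile, not an error.
- Turning-point detection (`detect_turning_point()`) exhaustively scans
  all change points of a two-piece fit — linear counts before, linear
  log-counts after — and accepts one only if the combined fit beats a
  single straight line by a likelihood-ratio criterion *and* the
  post-break growth rate is positive and exceeds the relative growth of
  the linear segment. Zeros are handled via `log(count + 1)`. Exhaustive
  search is O(n²) in the horizon, which is trivial at a few thousand
  ticks and exactly testable.
- `classify_fate()` partitions every trajectory: `extinct` (zero living
  cells at the horizon), `developed` (a turning point plus a final count
  at least ten times the pre-transition maximum — the tenfold factor is a
  documented constant), else `arrested`.

## Known limitations

- The binding floor, secretion shutdown in moribund cells, the fed-tick
  division clock, and per-species clearance are calibration-level rules
  the underlying qualitative model does not uniquely determine; each is
  motivated above and all are plain parameters that can be switched off.
- Vessels are cell chains without lumina or flow; anastomosis joins
  topology but has no hemodynamic consequence.
- Necrotic debris is never cleared, so late-stage tumors carry their full
  necrotic history.
- At very long horizons a rescued tumor keeps growing until it reaches
  the world boundary; the box, not the biology, sets the carrying
  capacity.
- The problem sizes used throughout the tests — 100³ worlds for the full
  scenario suite, 9³–41³ worlds for the field and behavior unit tests,
  1200-tick horizons — are the package's shipped study conditions; the
  acceptance script (`scripts/acceptance.R`) re-runs the four high/low
  secretion scenarios at full scale.
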