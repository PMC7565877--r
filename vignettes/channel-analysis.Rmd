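---
title: "Channel geometry, ligand diffusion states, and base-pair melting with ntpflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel geometry, ligand diffusion states, and base-pair melting with ntpflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntpflow)
```

## The problem

Multi-subunit RNA polymerases load their nucleoside-triphosphate (NTP)
substrates through internal channels: the secondary channel (CH2) running
from the enzyme surface to the active site, and a set of subchannels
(CH3A–D) converging on a pocket near the downstream DNA. Three questions
recur when analysing molecular-dynamics trajectories of such systems:

1. **Geometry** — how wide is each channel along its length, frame by
   frame, and where are its constrictions?
2. **Diffusion states** — which residue patches ("macro-regions") does each
   free ligand touch in each frame, how many ligands sit in each region on
   average, and which ligands achieve partial or complete loading?
3. **DNA availability** — are the downstream template bases paired,
   partially melted, or melted, and does a ligand's presence in the
   downstream pocket change those fractions?

`ntpflow` implements all three analyses plus a synthetic-data module that
generates inputs with known ground truth, so every stage is testable
without access to the original (unpublished) trajectories.

## The pathway-exploration algorithm

The channel axis is traced by iterative clearance maximization. The
*signed clearance* of a probe point $p$ in a structure with atom centers
$a_i$ and van der Waals radii $r_i$ is

$$c(p) = \min_i \left( \lVert p - a_i \rVert - r_i \right),$$

negative iff $p$ lies inside an atom. From the current path point, 64
candidate points are placed at `step_length` along quasi-uniform
(Fibonacci-spiral) directions on the hemisphere facing the target; the
candidate with maximal clearance, subject to net progress toward the
target of at least a quarter step, is refined by coordinate descent within
the disc orthogonal to the step direction, and accepted. The trace ends in
success within one step of the target, or is flagged `blocked` when no
candidate has positive clearance and progress (a sealed channel), or
`max_points`.

Design choices worth knowing:

* **Hemisphere + disc realization.** The original description ("iteratively
  calculate points at optimal distance from surrounding atoms") does not
  fix a search geometry. The hemisphere/disc realization was chosen
  because it is deterministic, cheap, and provably recovers the medial
  axis of tube-like cavities (the package's phantom tests check this
  against dense-grid maximization).
* **Determinism.** The candidate spiral's azimuthal offset is derived
  arithmetically from the seed; the global RNG is never consulted, so a
  fixed (structure, spec, seed) gives a bit-identical axis.
* **Signed clearance is not clamped.** MD frames can transiently clash;
  a negative clearance is diagnostic, not an error.
* **Tie-breaking** among equal-clearance candidates: greatest progress,
  then lowest candidate index.

### Minimal-radius profiles

`min_radius_profile()` tracks one axis over a trajectory window: per
frame, each path point is re-optimized only within the orthogonal disc
(radius `search_radius`) — the pathway is not re-discovered per frame,
matching the convention of monitoring a fixed route's width over time.
Clearances are binned at 1 Å by arclength measured **from the pathway
end** (the buried terminus), and the first 6 Å from the entry side are
trimmed by default: the first steps of the exploration converge from the
arbitrary start point onto the channel center, and their clearances
describe that convergence, not the channel. "Minimal radius" subtracts
van der Waals radii (surface distance); whether the original analysis
used surface or center distances is unstated, and the surface convention
is adopted here because it is the physically meaningful probe radius.

`constriction_report()` reduces a profile to the per-frame global minimum
and its location, plus per-bin temporal variance — segments with high
variance are the "circumstantial" ones whose opening depends on
conformation.

## Macro-region occupancy and events

The bundled region map (`default_region_graph()`) ships the MR1–MR20
topology: MR1–MR12 entry regions reachable from solvent, MR13 external
(bridging MR3 and MR12), MR14–MR18 infiltration regions, and the two
terminal areas MR19 (downstream pocket) and MR20 (active-site region).
Channel memberships follow the propensity-aggregate convention
(CH2 = MR1/2/3/4/14, CH3A = MR5/15, CH3B = MR6/7/16, CH3C = MR8/9/17,
CH3D = MR10/11/12/18). Residue selections are shipped empty — the
concrete residue lists are system- and numbering-specific — and only the
adjacencies stated in the source map's main description are encoded.

* **Contact criterion.** A ligand occupies a region iff any ligand heavy
  atom is within 4.0 Å of any region heavy atom. The original study's
  criterion is unstated; 4.0 Å heavy-atom is a standard contact distance,
  it is configurable, and the synthetic tests are cutoff-exact by
  construction.
* **Primary region.** When a ligand touches several regions at once, the
  deepest wins (terminal > infiltration > entry > external); ties go to
  the most recently entered region. This orders states from solvent
  toward the terminal areas.
* **Propensities.** Per region, the time-average and maximum simultaneous
  occupant count. Channel aggregates count *distinct ligands* per frame
  by default (a molecule touching MR2 and MR3 counts once toward CH2);
  the contact-sum convention is available with `dedup = FALSE` since the
  original convention is not stated.
* **Events.** Event detection runs on primary-region sequences only:
  `entry` (solvent to an entry region), `partial_loading` (an
  infiltration excursion that returns without reaching a terminal
  region), `complete_loading` (excursion reaches MR19/MR20), `exit`
  (return to solvent after infiltration). Transitions between regions not
  adjacent in the graph are flagged, not dropped — frame-sampled contact
  occupancy can legitimately skip an intermediate region between frames.

`occupancy_recovery_check()` closes the loop on synthetic data: for a
continuous-time jump model with generator $Q$, it compares estimated
per-region `mean_bound` against $n_\mathrm{lig}\,\pi_r$ (the stationary
law), with standard errors computed from the chain's autocovariance
$\operatorname{Cov}(\mathbf{1}_r(0), \mathbf{1}_r(l\Delta)) =
\pi_r\,(e^{Q l \Delta})_{rr} - \pi_r^2$ via the spectral decomposition of
$Q$ — naive i.i.d. standard errors would be badly anticonservative at
short frame intervals.

## Base-pair melting

`classify_pair()` applies a deliberately simple tri-state rule per frame:
a Watson–Crick hydrogen bond is intact iff its donor–acceptor heavy-atom
distance is at most 3.5 Å (no angle term); *associated* = all bonds
intact, *melted* = none, *partial* = otherwise. The distance-only
criterion keeps the classifier oracle-checkable, and matches the
distance-based restraint convention used to stabilize terminal base pairs
in such simulations. "Partial melting" as "some but not all bonds broken"
is the minimal consistent reading of a term the source uses without
definition — the study's own melting percentages are therefore not
reproduction targets for this package.

`melting_fractions()` reports per-register state fractions, the
cumulative partial+full melting fraction, and — when per-frame stratum
labels are supplied (typically "ligand present in the downstream pocket",
computed with `assign_states()`) — the same table per stratum. Strata
with zero frames are reported as absent, not as zero. Fractions sum to 1
to within 1e−9 by construction.

## The synthetic-data module

The generators state a world and are not tuned to test outcomes:

* **Channel phantoms** place rings of pseudo-atoms (radius 1.5 Å, 16 per
  ring, 0.75 Å ring spacing) at a wall radius around a straight or
  90°-bent centerline. Ground truth is the analytic centerline clearance
  `wall_radius(s) − atom_radius`. Ring discretization biases measured
  clearance upward by at most ~0.02 Å at these defaults. Ring spacing
  must not exceed the atom diameter, so no probe-sized gap opens.
* **Diffusion trajectories** evolve each ligand as an independent
  continuous-time Markov jump process on the region graph plus solvent,
  *observed* at frame times (not per-frame Bernoulli jumps), which
  preserves the stationary distribution exactly. Initial states are drawn
  from the stationary law so time averages are unbiased; a fixed initial
  state is available (and required for the degenerate zero-rate model).
  Ligand coordinates are the current region's anchor plus truncated
  Gaussian jitter, bounded so the ligand is provably within the contact
  cutoff of its region's pseudo-atoms and outside all others' (anchors
  must be more than twice the cutoff apart) — contact-based assignment
  therefore recovers the planted timeline *exactly*, which is what the
  round-trip tests assert. The default ligand count ties the fixtures to
  the experimental setup: 15 mM in a nominal cubic box of edge 120 Å
  gives 16 ligands (`ligands_from_concentration()`).
* **Melting series** plant per-frame states (exact counts via seeded
  permutation, or i.i.d. binomial draws) and realize them as bond
  distances: intact 2.9 ± 0.1 Å (clamped below 3.4), broken 8 ± 1 Å
  (clamped above 4.6), so any cutoff in [3.4, 4.5] classifies perfectly.
  Stratum multipliers scale the melted/partial probabilities within
  stratum "B", emulating a conditional contrast such as doubling of
  melting when a ligand occupies the downstream pocket.

What a green synthetic test does **not** establish: phantoms have no
side-pockets, surface roughness, or conformational change; the jump model
has no spatial diffusion between regions (transit is instantaneous at
frame resolution, so region-skipping transitions are expected and
flagged, not suppressed); melting series have no autocorrelated bond
dynamics. Real-trajectory behaviour on those axes is outside what the
test suite can certify.

## Numerical notes and limitations

* PDB coordinates carry three decimals; a write/read round trip is exact
  to 1e−3 Å. Per-atom van der Waals radii are *not* stored in PDB — a
  phantom with non-Bondi atom radius re-read from disk will be assigned
  table radii (override per element via `radius_table`).
* Binary trajectory formats (DCD/XTC) are not read; convert to
  multi-model PDB upstream. mmCIF is out of scope.
* Clearance includes all atoms present (hydrogens included when the
  structure has them); contact-based occupancy uses heavy atoms only.
  Whether the original clearance analysis included hydrogens is unstated;
  this is the documented default, switchable by stripping hydrogens from
  the input.
* `find_path` is a local greedy optimizer: it follows tube-like cavities
  reliably but is not an exact medial-axis (Voronoi) computation and can
  fail in cavities wider than `search_radius` with competing lobes.
  Automatic channel discovery without a start/target hint is a non-goal.
* The stationary-law check requires every region to be connected to
  solvent through positive rates; the degenerate zero-rate model needs an
  explicit initial state.
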