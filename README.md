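# ntpflow

Analytics for substrate-loading studies of multi-subunit RNA polymerases
(and channel-bearing proteins generally). Polymerases admit their NTP
substrates through internal channels — the secondary channel (CH2) to the
active site and subchannels (CH3A–D) converging on a downstream pocket —
and trajectory studies of that process keep re-implementing the same three
bespoke analyses. `ntpflow` packages them, tested:

* **Channel geometry.** A pathway-exploration algorithm traces the most
  central axis of a channel by iteratively maximizing the signed clearance
  `c(p) = min_i (‖p − a_i‖ − r_i)` over candidate steps toward a buried
  target, then extracts the **minimal radius along the pathway axis** per
  trajectory frame (1 Å bins by arclength from the pathway end, first 6 Å
  from the entry side trimmed), and reports constrictions and their
  temporal variance.
* **Ligand diffusion states.** Contact-based (4 Å heavy-atom) per-frame
  macro-region occupancy per ligand over an MR1–MR20-style region graph;
  binding propensities (time-average and maximum simultaneous ligands per
  region and per channel); directed transition graphs; and detection of
  entry, partial-loading, complete-loading (terminal regions MR19/MR20),
  and exit events.
* **Base-pair melting.** Tri-state Watson–Crick classification per frame
  (associated / partial / melted, 3.5 Å donor–acceptor bonds) with
  per-register time fractions, optionally stratified by ligand state
  (e.g. NTP present in the downstream pocket).
* **Synthetic ground truth.** Channel phantoms with analytic clearance,
  continuous-time jump-process diffusion trajectories whose planted
  timeline is recovered exactly by the contact assignment, and planted
  melting series — every analysis stage is testable without external
  data.

## Worked example

Plant a 1.0 Å constriction at arclength 15 in a 30 Å phantom channel,
trace the axis, and profile it:

```r
library(ntpflow)
wc <- wall_constriction(base = 4, min_wall = 2.5, at = 15, width = 2)
ph <- make_channel_phantom(channel_phantom_spec(
  length = 30, shape = "straight", wall_radius = wc))
ax <- find_path(ph$structure,
                pathway_spec(ph$start, ph$target, step_length = 1,
                             search_radius = 2), seed = 1)
ax
#> PathwayAxis: 30 points, length 29.2 A, status reached
pr <- min_radius_profile(ax, ph$structure, trim_start = 6)
round(constriction_report(pr)$per_frame, 3)
#>   frame frame_time arclength_from_end arclength_from_start min_radius
#> 1     1          0               14.5               14.731      1.035
```

The planted constriction (wall 2.5 Å − atom radius 1.5 Å = 1.0 Å clear)
is recovered at 1.035 Å, 14.7 Å from the entry — within a bin of the
planted 15 Å.

Simulate 8 ligands hopping between two regions and solvent at symmetric
rates (stationary occupancy 1/3 each), re-assign states from coordinates,
and check recovery:

```r
m <- diffusion_model_spec(
  regions = c("MR2", "MR3"),
  rates = c("solvent->MR2" = 1, "MR2->solvent" = 1,
            "solvent->MR3" = 1, "MR3->solvent" = 1),
  n_ligands = 8, frame_interval = 0.5, n_frames = 5000, seed = 42)
sim <- make_diffusion_trajectory(m)
tl <- assign_states(sim$traj, sim$graph, cutoff = 4)
identical(tl$primary, sim$truth$primary)   # exact round trip
#> [1] TRUE
occupancy_recovery_check(m, tl)
#>   region estimate expectation    se      z
#> 1    MR2    2.642       2.667 0.035 -0.715
#> 2    MR3    2.683       2.667 0.035  0.472
```

Estimated mean occupancies sit well within 3 autocorrelation-aware
standard errors of the analytic 8/3. Finally, recover a planted melting
plan exactly:

```r
g <- make_basepair_series(melt_series_spec(
  list(list(label = "i+3", n_bonds = 3, p_melted = 0.3, p_partial = 0.2)),
  n_frames = 1000, mode = "exact", seed = 3))
melting_fractions(classify_series(g$traj, g$pairs))
#>   register stratum n_frames f_associated f_partial f_melted f_cumulative_melting
#> 1      i+3    <NA>     1000          0.5       0.2      0.3                  0.5
```

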