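---
title: "Quantifying aggregate dynamics, cluster fusion and hydrogelation kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying aggregate dynamics, cluster fusion and hydrogelation kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelkin)
```

# The system and what gets measured

Human islet amyloid polypeptide (hIAPP) phase-separates into liquid droplets
at hydrophobic–hydrophilic interfaces such as the air–water interface (AWI),
and the droplets mature into a percolating hydrogel via amyloid aggregation.
Two instruments observe this process:

* **Oscillatory rheology** of the bulk records the storage and loss moduli
  G′ and G″ (Pa) over time. Hydrogelation appears as a lag, a roughly linear
  rise of G′ at some rate (Pa/h), and a plateau; a formed gel shows
  G′ > G″ (tan δ = G″/G′ < 1) and frequency-independent moduli.
* **Time-lapse confocal imaging** at the AWI shows fluorescent aggregates
  that accumulate, move in cluster-correlated local flows, form clusters of
  co-moving ("connected") aggregates that grow and fuse, and finally arrest
  as the whole field gels.

`gelkin` implements the quantification for both: trajectory-based speed
profiles and mobility-arrest gelation times, co-direction connectivity
graphs, cluster lineages with fusion onset/completion timing,
rheological feature extraction and kinetic-regime classification,
between-replicate heterogeneity (coefficient of variation, CoV) profiles,
and the hard-sphere excluded-volume arithmetic for macromolecular crowders.
Because imaging and rheology raw data of this kind are rarely deposited,
the package ships a synthetic generator with known ground truth; every
stage is validated by parameter recovery against that truth.

# The synthetic particle field

`simulate_particle_field()` generates what the microscope assay shows,
with these modelling choices:

* **Geometry.** The analysis plane is the 2-D interface (matching
  maximum-intensity z-projections); a z column is carried but zero. The
  field defaults to 1417 × 1417 µm², coordinates in µm with the origin at a
  field corner, frames 0-based, time = frame × Δt.
* **Clusters and flow.** Each cluster has a constant local-flow vector of
  magnitude `flow_amplitude` (default 3 µm/min, a typical interfacial
  aggregate speed on these length scales); members share that drift and add
  independent Gaussian localisation jitter (`jitter_sd`, default 0.3 µm,
  i.e. ~0.2 px at the 1.38 µm pixel pitch of a 1024-px field — sub-pixel
  centroiding noise, not Brownian motion).
* **Accumulation.** Clusters start with `n_initial` aggregates and gain
  new ones as a Poisson process (`nucleation_rate`, default 2 per cluster
  per hour) until gelation; new members appear on the cluster disc and
  adopt its flow. Particle count is therefore non-decreasing.
* **Arrest.** Mobility arrest is progressive, mirroring aggregates that
  become "progressively immobile": all drift is scaled by a multiplier that
  ramps linearly from 1 to 0 over `arrest_ramp` (default 0.25 h) ending
  exactly at `gelation_time`, so displacements after the gelation time are
  identically zero (up to jitter). `gelation_time = Inf` gives a
  never-gelling record.
* **Fusion.** A scheduled fusion `(a, b, onset, duration)` places the pair
  on converging straight paths that reach `contact_distance` (default
  60 µm) exactly at the onset, with headings 135° apart so the pair reads
  as anti-directional while approaching. At onset the single contact
  aggregate of `b` adopts `a`'s flow (the first co-directional contact);
  at `onset + duration` the rest of `b` follows (completion). The 135°
  offset is deliberate: with ±60° co-direction cones, a window-averaged
  direction rotating between two headings ≥120° apart can never sit in
  both cones at once, so the switching aggregate cannot spuriously bridge
  the two clusters.
* **Frame interval.** 3 min for gelation-scale runs (hours), 0.2 min for
  fusion-scale runs — completion durations of ~0.8–4.4 min need sub-minute
  sampling. The acquisition interval of the original z-stack series is not
  knowable from the data, so these are the package's own defaults.

What the generator does **not** emulate: droplet-scale phase-separation
physics, Ostwald ripening, fibril structure, photon (shot) noise,
photobleaching, aggregate shape, or z-dependent optics. Passing the
recovery tests therefore shows the *quantification* is correct and robust
to localisation jitter and Poisson accumulation — not that the generator is
a faithful forward model of raw microscopy.

# Tracking and the mobility-arrest gelation time

`detect_particles()` finds thresholded 3×3 local maxima and refines them
with an intensity-weighted centroid (window ±2σ, duplicates within one σ
merged); on noiseless rendered spots the error is well under 0.1 px.
`link_trajectories()` uses greedy mutual-nearest-neighbour linking under a
`max_disp` gate with optional gap closing — O(n log n)-ish in practice, and
demanded to equal a brute-force optimal assignment only at small n, where
ambiguity is absent.

`compute_speed_profile()` subtracts, per frame pair, the arithmetic mean
displacement vector of all particles present in both frames (the "mean
flow"); each particle's flow-subtracted speed is the magnitude of its
residual displacement over Δt, and the replicate curve is the per-pair mean.
Residuals sum to zero by construction — that invariant is tested at 1e-9
relative tolerance. The mean flow is global per frame pair: the plotted
correction in this assay is a single mean-flow curve, and a per-cluster
variant adds estimation noise without changing the replicate summary.
Frame-pair quantities are timestamped at the pair midpoint
(central-difference convention), which makes the arrest estimate centred
rather than systematically late.

`estimate_gelation_time()` declares gelation at the earliest profile time
from which the mean speed stays at or below a threshold until the end of
the record, with at least `persistence_h` (default 0.5 h) of quiescent
evidence. The threshold is `threshold_frac` (default 0.1) times the 90th
percentile of the mean speed over the first quarter of the record, floored
at `noise_floor` (0.05 µm/min). The assay reports mobility duration without
an operational criterion, so these defaults were chosen once for robustness
to the jitter floor: at default noise the post-arrest jitter speed is
≈0.18 µm/min while the threshold sits at ≈0.3 µm/min. A record whose first
profile point is already quiescent returns 0; a record that never
quiesces (or quiesces with less than the persistence window remaining)
returns "not gelled". A 1e-9 relative guard on the threshold comparison
keeps exact ramp-boundary cases platform-stable.

# Connectivity, lineages and fusion events

`displacement_vectors()` estimates directions over a 5-frame-pair window
(default) — long enough to average jitter (direction noise ≈8° at default
settings), short enough to resolve sub-minute fusion. Pairs within
`neighbour_radius` (150 µm) whose speeds clear a minimum-motion floor are
labelled *connected* when the cosine similarity is ≥ +0.5 and
*non-connected* at ≤ −0.5 (±60° cones; the assay's classification is
binary same/opposite with no angle stated, so the cut is symmetric and
configurable). Clusters are connected components over connected edges
(via igraph), ordered by size then smallest member id.

`track_lineages()` matches clusters window-to-window by Jaccard overlap
(threshold 0.3 — loose enough to survive membership churn at default
jitter, strict enough not to teleport identity); many-to-one matches are
merges. `detect_fusion_events()` then times each merge:

* **Onset** is the first "connected" edge between members of the two
  parents. Membership is taken as the union over the preceding
  direction-window's worth of windows, because the first co-aligning
  aggregate is reassigned to the partner's component in the very window
  its contact edge appears (and can transit a one-window singleton state
  while its direction rotates between cones).
* **Completion** is the first window from which all parent members move as
  a single cluster for at least `persistence` (5) consecutive windows —
  the assay reports completion durations without defining the criterion,
  and stable single-component persistence is the natural operationalisation.
* Merges whose parents are smaller than `min_parent_size` (2) or younger
  than `min_parent_age` (= persistence) windows are growth or flicker, not
  fusion; and a merge that adds fewer than `min_parent_size` members beyond
  an earlier event's union is the same fusion re-observed after a transient
  split. These three rules make detection exact (precision = recall = 1)
  over 20 seeds at default noise while leaving genuine chained fusions
  (which add a whole new cluster) untouched.

`summarize_fusion()` aggregates per replicate (events are per-event, as in
the per-event scatter convention), then per condition: grand means over
replicate means, SEM across replicate means, within-replicate SDs, and
direction-flagged fold changes versus the control — a condition mean below
the control is an acceleration reported as control/condition, above it a
delay reported as condition/control, both as ratios ≥ 1 rounded half-up to
one decimal (the convention such tables are printed in), with raw ratios
retained.

# Rheology features

`simulate_rheology_trace()` draws the canonical piecewise-linear gelation
curve: baseline (0.02 Pa) to `lag`, linear rise at `rate_gp` to
`plateau_gp`, flat thereafter, with G″ rising at its own rate to a
configurable fraction (0.3) of the G′ plateau, plus Gaussian noise.

`extract_gelation_features()` works in four steps:

1. **Baseline.** Median over an adaptive initial stretch — the candidate
   stretch (5, 7, 10, 15 points up to `baseline_window`) with minimal MAD —
   so a lag shorter than the declared window does not contaminate the
   estimate.
2. **Rise location.** First exceedance of baseline + `mad_mult` × MAD
   (default 5×) sustained for `lag_persistence` (0.25 h) on the raw trace,
   used only to locate the rise and bound the lag.
3. **Rate.** Least-squares slope of the *raw* trace over the central
   15–85% of the baseline-to-plateau span (span located on a 0.5 h centered
   moving average). A maximum over sliding-window fits was rejected: the
   max of many noisy slopes is strongly biased upward (at 5%-of-plateau
   noise the per-window slope noise alone exceeds the slow-regime rate),
   whereas the central-rise fit is identical on noiseless piecewise-linear
   traces and keeps the median rate error under 10% in the noise tests.
4. **Lag.** The rise line back-projected onto the baseline level, with the
   baseline then re-estimated over the pre-lag points and the projection
   repeated once. A pure threshold-persistence lag was rejected for the
   same reason as the sliding-window rate: with a slow rise, any threshold
   a noisy baseline supports is crossed hours after the true onset. On
   noiseless traces the back-projection is exact; on step-like traces it
   lands within one grid step of the step.

The plateau is the mean of the trailing segment where the smoothed
derivative stays below 5% of the rate; tan δ at plateau is the mean G″/G′
there. The extraction is scale-equivariant (trace × c ⇒ rate and plateau
× c, lag unchanged) and shift-equivariant (time + Δ ⇒ lag and plateau
onset + Δ) — both are property tests. A trace that never sustains a rise
is flagged `regime = "none"` with NA features, never silent zeros.

`classify_regime()` cuts at 0.45 and 2.0 Pa/h. These are induced from the
observed rates — slow 0.28–0.36, intermediate 0.50–1.12, fast 4.7 Pa/h —
i.e. data-derived defaults, and both are arguments. `assess_gel_state()`
scores a frequency sweep as a gel iff G′ > G″ at every tested frequency and
|d log G′ / d log ω| < 0.1.

# Heterogeneity

`align_replicates()` interpolates linearly onto a common grid inside the
overlapping time span only (no extrapolation). `cov_profile()` uses the
sample SD (n−1; replicate counts here are 3–6) over the mean per time
point, masking columns whose |mean| is below `mean_floor` — default 5% of
the global maximum — because CoV diverges where the measured quantity is
near zero. `two_sample_t()` wraps `stats::t.test` — Welch by default (the
assay's "two-sample t-test" does not specify a variant; Welch is the safe
default, pooled is available), two-sided, with the two-zero-variance
degenerate case flagged instead of erroring.

For the qualitative two-regime contrast (the condition-level raw data are
not deposited), `simulate_regime_ensemble()` draws six replicates from the
fast/slow mixture at p = 0.5 against three homogeneous intermediate
replicates — the replicate counts used per condition — with instrument
noise of 2% of plateau, chosen once as a realistic rheometer noise level
(separately, the feature-extraction robustness tests run at the harsher 5%).
The mixture's maximum CoV exceeds the homogeneous ensemble's in ≥18 of 20
seed pairs; the few losses are mixture draws that happen to be all one
regime, which are genuinely indistinguishable from homogeneous kinetics.

# Crowding arithmetic

The crowder is a hard sphere of its Stokes radius (58 Å for dextran 70 kDa,
100 Å for Ficoll 400 kDa) — exactly the published arithmetic, with no
polymer-coil correction. % w/v is g per 100 ml (6% = 60 g/l), the only
reading consistent with the printed molecule counts. The chain is
count = c·V·N_A/MW → V_occ = count·(4π/3)r³ → c_eff = c₀·V/(V−V_occ).
`crowding_analysis()` applies the sphere volume to the count *as reported
at 3 significant figures* — that is how the printed chain proceeds, and at
full count precision the dextran volume rounds to 146 µl rather than the
printed 145 — while keeping the fully unrounded volume alongside and all
downstream quantities unrounded until reporting (nearest µl, one-decimal
µM and ratios, half-up).

# Problem sizes and runtime choices

Gelation-scale runs use 7 h at 3-min frames (141 frames, ~50–90
aggregates); fusion-scale runs 36–45 min at 0.2-min frames with five
clusters of ~10 aggregates; noise robustness uses 20-seed batteries and
50 noisy rheology traces. These sizes make every recovery statistic stable
at three decimals while keeping the whole battery fast on a single CPU.

# Known limitations

* The generator's fusion geometry is stylised (straight approach paths,
  instantaneous drift switching); real cluster fusion involves deformation
  and partial coalescence the detector never sees here.
* Lineage tracking assumes clusters evolve gradually between consecutive
  windows; acquisition gaps much longer than the direction window would
  break the Jaccard matching.
* The mean flow is global; strong counter-rotating local flows would
  leak into flow-subtracted speeds (a per-cluster correction would need
  cluster labels upstream of speed profiling).
* The excluded-volume model ignores crowder polydispersity, hydration and
  coil interpenetration; it reproduces a printed arithmetic, not a
  thermodynamic theory.
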