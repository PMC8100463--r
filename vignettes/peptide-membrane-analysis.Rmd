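---
title: "Analysing membrane-bound IAPP trajectories: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing membrane-bound IAPP trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepMembrane)
```

# The scientific setting

Islet amyloid polypeptide (IAPP, amylin) is a 37-residue peptide that binds
lipid bilayers as an amphipathic helix, with its hydrophobic face (Ala8,
Leu12, Phe15, Leu16, Phe23, Ile26, Leu27) buried at the
hydrophobic/hydrophilic interface. How deeply the helix sits in the
membrane, and how the lipid species around it rearrange, depends on the
bilayer composition — notably on cholesterol (CHOL), which orders and
thickens phosphatidylcholine (DOPC) membranes, and on anionic
phosphatidylserine (DOPS), which interacts with the peptide's cationic
groups (the N-terminus, Lys1, Arg11).

pepMembrane implements the complete analysis chain used to characterise
this system from molecular-dynamics trajectories:

* per-residue **helicity** (dihedral criterion), helical-residue counts per
  segment, helical wheels;
* per-residue **insertion depth** relative to the phosphate plane, with
  between-condition difference profiles and significance bands;
* four **membrane properties**: area per lipid, lateral diffusion
  coefficient, acyl-chain order parameter, bilayer thickness;
* the **depletion-enrichment (D-E) index** of each lipid species in shells
  around the membrane-binding part of the peptide (residues 1–19), with a
  one-sample t test against 1;
* geometric clustering of the disulfide-looped N-terminus into
  **orientation states** (O1/O2), 3D **occupancy maps** of each lipid
  species in the peptide-aligned frame, and distance-fingerprint clustering
  of peptide–lipid **binding modes**.

Because the microsecond atomistic trajectories behind such analyses are not
reproducible at desk scale, the package ships a synthetic trajectory
generator with fully planted ground truth. Every analysis stage has a
parameter-recovery test against quantities the generator planted, not
against numbers any particular simulation happened to produce.

# Coordinate conventions

Everything internal is in Angstrom with z as the bilayer normal; thickness
is additionally reported in nm at the output layer. Residues are numbered
1–37 (Lys1…Tyr37). Periodicity is applied laterally (x, y) only: all
shell and contact analyses live within one leaflet's neighbourhood, and
wrapping z would spuriously join the two leaflets.

Leaflets are assigned by splitting the phospholipid phosphate z values at
the midpoint of their largest gap (a robust bimodality split; a gap below
8 Å raises a "monolayer or unwrapped system" error). Cholesterol carries no
phosphate and joins the leaflet of its nearest phosphate. The *bound*
leaflet is the one whose phosphate plane is nearest the mean z of Cα 7–16,
the stable helical core.

# The analysis models and their assumptions

## Helicity

No hydrogen-bond (DSSP-type) assignment is attempted; a residue is helical
iff its (φ, ψ) pair falls in the window φ ∈ [−100°, −30°],
ψ ∈ [−80°, −5°] *and* it sits in a run of ≥ 3 consecutive in-window
residues. The window and run length are exposed in `assignHelical()`. This
criterion is self-contained, rotation-invariant and directly testable;
the cost is that absolute helicity values are not comparable with
DSSP-based numbers, so only the qualitative structure of helicity profiles
should be compared across software. Chain termini, lacking φ or ψ, are
never helical. The helicity fraction pools repeats frame-weighted
(accumulated simulation time), and segment counts (residues 1–19 vs 20–37)
are summarised over the final half of each trajectory by default — the
window in which such simulations are typically equilibrated.

## Insertion depth

The phosphate plane is the per-frame arithmetic mean z of the bound
leaflet's phosphates (`mode = "both"` is available; a both-leaflet plane
sits mid-membrane and is rarely what is wanted). The signed distance of
each Cα to the plane is positive toward water, negative toward the acyl
tails. The statistical unit for condition comparisons is the per-repeat
time mean: frames are heavily autocorrelated, so `deltaProfile()` treats
the repeats (typically n = 4 per condition) as the observations and uses
Welch's unequal-variance two-sided t test by default (`varEqual = TRUE`
switches to the pooled test). Bands follow the fixed thresholds
significant p ≤ 0.05, marginal 0.05 < p < 0.10, nonsignificant p ≥ 0.10.

## Membrane properties

* **Area per lipid** = lateral box area / lipids per leaflet, averaged over
  leaflets. Whether cholesterol counts in the denominator is a convention
  that differs between tools; `countChol = TRUE` is the default and the
  flag is exposed.
* **Lateral diffusion**: MSD(τ) over molecules and all time origins
  (FFT accumulation; `originStride` switches to strided direct sums),
  after unwrapping and removing each leaflet's lateral centre-of-mass
  drift (leaflets can drift oppositely, inflating D). D = slope/4 from a
  least-squares fit over 10–50 % of the maximum lag — the standard window
  avoiding short-time ballistic/caging effects and poorly averaged long
  lags. 1 Å²/ps = 10⁻⁴ cm²/s.
* **Order parameter** S = ⟨(3 cos²θ − 1)/2⟩ of tail segment vectors
  (atom i−1 → i+1) against the bilayer normal; sign retained, bounds
  [−0.5, 1].
* **Thickness** = distance between the phosphate-density peaks of the two
  leaflets: pooled per-leaflet histograms (bin 0.5 Å), Gaussian smoothing
  (σ = 1 Å), parabolic sub-bin peak interpolation to remove bin-width
  bias.

## Depletion-enrichment index

D-E(species, r) = (in-shell fraction of the species) / (bulk fraction in
the bound leaflet). A lipid is in-shell iff *any* of its atoms is within r
of *any* atom of residues 1–19 (the shell criterion names no atom subset,
so the most inclusive reading is used and documented). Shells are
cumulative (0–r) at r = 7, 14, 21 Å by default — the three nearest lipid
shells — with an annular option. Counts are summed over frames before the
ratio is formed ("ratio of sums"): per-frame ratios are unstable when few
lipids are in the shell; the per-frame variant is available. Bulk
composition is taken from the bound leaflet because the peptide samples
only that leaflet; both-leaflet normalisation would bias D-E whenever the
leaflets differ. Significance is the two-sided one-sample t test of the
per-repeat values against 1.

## Loop orientation and binding modes

The N-terminal loop (residues 1–7, closed by the Cys2–Cys7 disulfide in
the real peptide) swings to either side of the helix. Its side is
quantified by a signed chirality: with û the least-squares axis through
Cα 7–16 (oriented N→C) and ẑ the membrane normal toward water, the loop
displacement v (Cα 1–5 centroid off the axis) gives chirality v · (ẑ × û);
mirror-image loops negate it exactly. Clustering pools frames across all
conditions, aligns on Cα 7–16, and applies average-linkage hierarchical
clustering on pairwise Cα 1–7 RMSD, cut at 2.5 Å. The two largest clusters
are labelled O1/O2 by the sign of their median chirality — anchoring the
labels to geometry rather than cluster indices keeps them stable across
reruns. Everything else is "other" and excluded from orientation-
conditioned occupancy maps.

Binding modes are clustered on 19-component fingerprints: per residue of
1–19, the minimum atom–atom distance to the lipid, capped at 10 Å; only
lipids within 4.5 Å of the selection (an "engaged" pair) are emitted, at a
default stride of 10 frames to tame autocorrelation. Average-linkage
hierarchical clustering with the Euclidean metric, tree cut at 8 Å,
clusters holding ≥ 1 % of pairs catalogued largest-first (top 5), with
per-series contribution fractions (row-stochastic). Phospholipids
(DOPC + DOPS, species recorded) and cholesterol are clustered separately —
their interaction chemistry differs qualitatively. All cutoffs are
arguments; they are deterministic, standard choices rather than values
recovered from any particular study, and exact reproduction of published
mode inventories is not expected.

## Occupancy maps

After aligning every frame on Cα 7–16 against a common reference (frame 1
of the first repeat by default), selected lipid atoms are binned into a
1 Å voxel grid extending 15 Å beyond the peptide bounding box; each voxel
stores the fraction of frames in which at least one selected atom was
present (per-frame presence, so occupancy never exceeds 1). Grids are
written in plain-text OpenDX, loadable in standard molecular viewers.

# The synthetic generator: what it emulates, and what it does not

`syntheticConfig()` defaults describe the studied conditions: an
80 × 80 Å patch, 100 lipids per leaflet, DOPC/DOPS/CHOL 45–15–40,
phosphate planes at ±19 Å (3.8 nm), phosphate z noise σ = 1 Å, species
diffusion 7 / 5.5 / 3.5 × 10⁻⁸ cm²/s, frames 400 ps apart over 1 μs, and a
straight membrane-bound helix spanning residues 7–28 (the kinked variant
uses 7–18 plus 23–28). Lipids are coarse proxies — a head bead (phosphate,
or a hydroxyl bead for cholesterol, placed 3 Å deeper) and a straight run
of tail beads realising a sampled orientation — because every analysis in
scope consumes only head positions, tail vectors and whole-lipid
proximity.

Planted features and how they are realised:

* **Diffusion**: per-axis Gaussian steps of variance 2·D·dt; unwrapped
  tracks are kept as ground truth.
* **Order**: tail directions drawn from the Maier–Saupe-type family
  ∝ exp(λ cos²θ); λ is found by numerically inverting the λ → S map, so
  the sample order parameter converges to the target.
* **Depth**: in `"depth"` mode Cα sit exactly at the per-residue profile
  plus Gaussian noise (backbone atoms are decorative); in `"helix"` mode
  the backbone is a genuine ideal α-helix (φ = −57°, ψ = −47°, exact
  100°/1.5 Å parametric geometry) whose axis is placed at the segment-mean
  depth, with coil residues rebuilt each frame at dihedrals drawn outside
  the helical window — so the planted helicity schedule is recovered
  exactly, by construction.
* **Loop states**: two rigid loop templates hang off the helix anchor; the
  second is the first rotated half a turn about the helix-axis direction
  through the junction carbon, which preserves the anchor's φ while
  flipping the chirality sign exactly. A Markov chain with the configured
  stationary probabilities (default 0.38/0.35, remainder diffuse) drives
  per-frame states; diffuse frames swing the loop to angles at least 30°
  away from both planted orientations.
* **Enrichment**: with an enrichment factor ≠ 1 the generator switches to
  per-frame equilibrium placement (the D-E index is a time-averaged
  composition ratio, so equilibrium placement is sufficient and exactly
  controllable; with Brownian placement a biased *density* would require
  biased dynamics). Placement is rejection sampling whose in-shell
  criterion is identical to the one the D-E analysis measures (any-bead
  3D distance to any atom of residues 1–19). A first unbiased pass
  measures the shell's probability mass q, and the target's in-shell
  acceptance weight is set to ρ = G(1−q)/(1−Gq) with
  G = factor·(1−f)/(1−factor·f): this finite-shell-size correction makes
  the planted in-shell composition equal factor × bulk exactly in
  expectation, for any shell geometry.
* **Binding modes**: one designated lipid per mode is teleported, in a
  Bernoulli-chosen fraction of frames, to a pose contacting the configured
  residues; the planted pose includes the tail orientation (straight
  down), since a binding mode is a whole-lipid configuration.

What the generator does **not** emulate: forces, thermostats or any
physical dynamics; realistic lipid chemistry; peptide conformational
kinetics (helical segments are rigid); membrane undulations and defects;
correlated lipid motion. Passing recovery tests therefore demonstrates
that the analysis code measures what it claims to measure on data with
known structure — it does not validate force fields or sampling of real
simulations, and absolute values from real trajectories still require the
usual convergence checks.

# Numerical choices

* Minimum-image wrapping maps displacements into [−L/2, L/2) (floor
  convention; the half-box boundary goes to −L/2).
* The ideal-helix backbone uses frozen cylindrical offsets for N, C and O
  relative to Cα, derived once from a natural-extension (NeRF) chain at
  ideal bond geometry; at the exact 100°/1.5 Å parametric helix the
  interior dihedrals come out within 0.3° of (−57°, −47°).
* MSD uses the exact FFT decomposition MSD(τ) = S1(τ) − 2·S2(τ); it is
  verified against a brute-force double loop in the tests.
* Thickness peaks use parabolic three-point interpolation; degenerate
  curvature falls back to the bin centre.
* Hierarchical clustering is `stats::hclust` (average linkage) with
  deterministic size-ordering of clusters; ties break toward the lowest
  original index, so reruns are bit-identical.
* Welch p-values come from `stats::t.test`; two series with zero variance
  get p = 1 (equal means) or p = 0 (different means) by convention.
* The one-parameter angular family is sampled by rejection against the
  uniform; λ is capped at values where the acceptance rate is still
  practical, and the exact limits S = 1 and S = −0.5 are special-cased.

# Open design points, resolved

* The phosphate plane could use one or both leaflets; the bound leaflet is
  the default and the option is exposed (`mode = "both"`).
* Whether the published area-per-lipid convention counted cholesterol is
  unknowable from the analysis description alone; both conventions are
  implemented behind `countChol`.
* Cumulative vs annular D-E shells: cumulative is the default reading of
  "within 7, 14, 21 Å"; `annular = TRUE` gives 0–7/7–14/14–21.
* Welch vs pooled variance for the insertion comparison: Welch by default
  (4 repeats give no basis for assuming equal variances), switchable.
* The loop/binding-mode clustering algorithm details are fixed here as
  average-linkage with RMSD (cut 2.5 Å) and Euclidean fingerprints (cut
  8 Å, engagement 4.5 Å, cap 10 Å, minimum cluster 1 %); all exposed.

# Validation problem sizes

The shipped test-suite recovery experiments use, per stage: 5,000-frame
walks of 200 lipids for diffusion (recovery within 10 %); 4-repeat series
of 300 frames × 80 lipids for the planted 2× enrichment (within 10 %);
1,000 replications of 4-repeat null series for the size of the one-sample
D-E test (5 % ± 2 %); 10,000 null residue comparisons for the Welch test
size (5 % ± 1 %); 2,000 frames for depth-profile recovery (within 0.2 Å);
5,000 pooled frames for loop-orientation fractions (within ±0.05); and a
four-condition, 4 × 250-frame end-to-end study whose report must recover
every planted quantity and be byte-identical across reruns. These sizes
were chosen so each check is decisively powered while the whole suite
remains quick on a single CPU.

# Limitations

* The dihedral helicity criterion is not DSSP; absolute helicity levels
  differ from hydrogen-bond-based assignments.
* One peptide per system; multi-peptide and oligomerisation analyses are
  out of scope, as are triclinic boxes and velocities/forces.
* Trajectory IO covers GRO (topology and multi-frame text trajectories)
  and DCD; compressed XTC is not read — convert to DCD or multi-frame GRO
  first.
* D-E significance with n = 4 repeats has limited power; the test size is
  validated, not its power against small enrichments.
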