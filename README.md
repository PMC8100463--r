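# pepMembrane

Trajectory analysis for a membrane-bound amphipathic peptide — islet
amyloid polypeptide (IAPP, amylin) on planar DOPC/DOPS/cholesterol
bilayers — with a synthetic ground-truth generator so that every analysis
stage is verifiable by parameter recovery, without running molecular
dynamics.

IAPP is the 37-residue peptide whose membrane-catalysed aggregation is
implicated in type-II diabetes. Bound to a bilayer it forms an amphipathic
α-helix whose insertion depth below the phosphate plane, and whose local
lipid environment, depend on membrane composition: cholesterol orders and
thickens the membrane and pushes the helix out; anionic DOPS is drawn to
the peptide's cationic groups. The package implements the quantities used
to characterise this system from atomistic trajectories:

* **Helicity** — per-residue dihedral-window assignment (φ ∈ [−100°, −30°],
  ψ ∈ [−80°, −5°], runs ≥ 3), pooled helicity fractions, segment counts
  (residues 1–19 / 20–37, last-half mean ± SD), helical wheels with the
  hydrophobic face (Ala8, Leu12, Phe15, Leu16, Phe23, Ile26, Leu27).
* **Insertion** — signed Cα distance to the bound-leaflet phosphate plane;
  Δmembrane-distance profiles between conditions with Welch t tests over
  the per-repeat means and bands at p ≤ 0.05 / < 0.10 / ≥ 0.10.
* **Membrane properties** — area per lipid (box area / lipids per
  leaflet); lateral diffusion D = slope/4 of the drift-corrected MSD
  (fit over 10–50 % of the maximum lag; 1 Å²/ps = 10⁻⁴ cm²/s); acyl order
  parameter S = ⟨(3 cos²θ − 1)/2⟩; bilayer thickness from the distance
  between the two leaflets' phosphate-density peaks.
* **Depletion-enrichment index** — D-E(species, r) = in-shell fraction /
  bulk fraction at r = 7, 14, 21 Å around residues 1–19, one-sample t
  test against 1.
* **Conformers** — geometric clustering of the N-terminal loop into
  orientation states O1/O2 (signed chirality v·(ẑ×û) against the helix
  axis), 3D lipid occupancy maps in the Cα 7–16-aligned frame (OpenDX
  output), and binding-mode clustering of capped per-residue
  minimum-distance fingerprints of engaged peptide–lipid pairs.
* **Synthetic generator** — coarse-proxy bilayer + ideal-helix peptide
  with planted diffusion, order, depths, leaflets, loop states,
  enrichment and binding modes, fully determined by (config, seed).

## Worked example

Generate a four-repeat series of a PC/PS/CHOL membrane with a planted
two-fold DOPS enrichment within 7 Å of the peptide, then measure it:

```r
library(pepMembrane)

cfg <- syntheticConfig(
  nLipidsPerLeaflet = 50, nFrames = 300,
  composition = c(DOPC = 0.55, DOPS = 0.15, CHOL = 0.30),
  enrichment  = list(species = "DOPS", factor = 2, radius = 7),
  seed = 42)
ss <- syntheticSeries(cfg, nRepeats = 4, label = "PC/PS/CHOL")

deIndex(ss$series)
#>   species radius  mean        p
#> 1    CHOL      7 0.809 1.30e-03
#> 2    CHOL     14 0.916 5.09e-03
#> 3    CHOL     21 0.962 3.27e-03
#> 4    DOPC      7 0.818 7.27e-05
#> 5    DOPC     14 0.922 1.25e-04
#> 6    DOPC     21 0.969 4.80e-04
#> 7    DOPS      7 1.972 7.64e-05
#> 8    DOPS     14 1.421 1.83e-04
#> 9    DOPS     21 1.178 1.19e-04
```

The planted 2× enrichment is recovered at the 7 Å shell (1.97, p ≪ 0.05),
decays toward 1 with distance, and the other species are correspondingly
depleted. The same series yields the insertion profile and membrane
properties:

```r
prof <- residueProfile(ss$series)
round(prof$mean[c(8, 9, 12, 15)], 2)
#>     8     9    12    15
#> -4.27 -3.66 -4.81 -3.66        # hydrophobic-face residues sit deepest

tr <- trajectoryRepeats(ss$series)[[1]]
round(helicityFraction(helicityTrace(tr))[c(5, 10, 20, 30)], 2)
#> [1] 0 1 1 0                    # planted helix spans residues 7-28
orderParameter(tr)$average       # 0.4  (planted 0.4)
membraneThickness(tr) / 10       # 3.8 nm (planted phosphate planes at +-19 A)
```

A whole multi-condition study — helicity, insertion and Δ tables, membrane
properties, D-E tables, loop clusters, occupancy maps, binding-mode
catalogs, and a manifest with seeds and checksums — is produced by
`runStudy(studyConfig(...))`, or from the shell via
`Rscript scripts/run_study.R --config study.yaml --out report --seed 1`.
Reruns with the same configuration and seed are byte-identical.

Real trajectories are ingested with `readTopology()` (GRO/PDB) and
`readTrajectory()` (multi-frame GRO or DCD) and flow through the same
functions.

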