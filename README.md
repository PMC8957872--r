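# lipofold

Where do lipoquinones sit in a membrane, and how do they fold?
Ubiquinones (UQ) and menaquinones (MK) — the lipid electron carriers of
the respiratory chain — are usually drawn extended, but NMR and monolayer
evidence on truncated analogs (UQ-2, MK-2) points to folded, U-shaped
conformers anchored at the membrane-water interface.  `lipofold`
implements the complete desk-scale analysis chain behind that kind of
study, for spectroscopists and membrane biophysicists who want the
workup reproducible and testable:

* **NOE calibration** — cross-peak volume standardization against a
  reference pair with known distance (~3.5 Å), strong/medium/weak
  classes (>1.5 / 0.6–1.5 / <0.6 on normalized volume), distance bins
  (<3 / 3–4 / >4 Å), and the continuous isolated-spin-pair law
  r = r_ref·V^(−1/6) as a cross-check.
* **Conformer modeling** — idealized-geometry 3D models of UQ-n/MK-n,
  a seeded multi-start torsion-space optimizer against flat-bottom
  distance restraints, measurement of the headgroup–chain dihedral
  φ(C2C3CβCγ), Kabsch superposition, and classification into
  flat-extended / folded-extended / U-shaped (folded ⇔ |φ| ≈ 90° ± 30°;
  U-shaped ⇔ terminal methyls back over the headgroup).
* **Reverse-micelle localization** — Δδ arithmetic between organic,
  w₀-series reverse-micelle and aqueous environments, with a threshold
  rule assigning organic bulk / interface / water pool.
* **Langmuir isotherm workup** — π = γ₀ − γ, replicate averaging with
  SD at every 5 mN/m, per-phospholipid normalization A_N = A/x,
  compression modulus Cs⁻¹ = −A·dπ/dA, second-derivative collapse
  detection, and the 30–35 mN/m area-expansion metric.
* **Synthetic data** — seeded generators for NOE peak tables (volumes ∝
  d⁻⁶ with a 5 Å detection limit and lognormal noise), phase-model
  compression isotherms with known collapse pressure, and shift tables
  with known probe location, so every stage is testable without
  instrument output.

## Worked example

Simulate a noisy NOESY peak table from a known U-shaped UQ-2 conformer,
run the calibration → restraints → fit → classification chain, and check
the interfacial location from the published shift table:

```r
library(lipofold)

top   <- build_topology("UQ", 2)      # UQ-2 topology: 49 atoms (C19H26O4)
truth <- reference_conformer("U-shaped", top)
peaks <- simulate_peak_table(truth, cv = 0.2, seed = 7,
                             environment = "w0-12-RM")
head(peaks, 3)
#>   group_a group_b    volume spectrum environment overlap_flag
#> 1     H_W    H_MN 1.5424331    NOESY    w0-12-RM        FALSE
#> 2     H_W     H_B 0.1115201    NOESY    w0-12-RM        FALSE
#> 3     H_W     H_X 7.8795996    NOESY    w0-12-RM        FALSE

run <- run_noe_pipeline(peaks, top,
                        config = run_config(seed = 7, n_starts = 16),
                        expected_pairs = t(combn(names(top$proton_groups), 2)))
run$classification
#> conformation: U-shaped (phi = -100.0 deg, min terminal methyl-H_W distance 4.01 A)

localize(uq2_shift_table())
#> probe location: interface
#>   proton d_org d_aq      vote
#> 1    H_A  0.01 0.10 interface
#> 2    H_B  0.02 0.09 interface
```

The fit recovers the generating conformation class: a folded dihedral
(|φ| ≈ 100°, inside the 90° ± 30° window) with a terminal methyl 4 Å
from the ring methyl — a U-shaped conformer.  The shift rule reads the
published vinyl-proton table as "organic-like but measurably perturbed,
far from bulk water": the probe sits at the reverse-micelle interface.

The isotherm side works the same way from simulated trough replicates:

```r
iso <- simulate_isotherm(uq2_phase_model(scatter_sd = 0.5),
                         n_replicates = 3, seed = 7)
run_isotherm_pipeline(iso)
#> collapse pressure: 20.75 mN/m (d2A/dpi2 = -13.10, grid 0.25 mN/m)
#> max compression modulus: 44.7 mN/m
```

The detected collapse (20.75 mN/m) sits one grid step from the
generator's 21 mN/m plateau.  Preparation arithmetic is also covered:

```r
molarity(45.4, molar_mass("C19H26O4"), 10.0)   # mg, g/mol, ml -> mM
#> [1] 14.25821
```

See `vignettes/lipoquinone-analysis.Rmd` for the model, its assumptions,
parameter defaults and limitations.

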