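---
title: "Determining lipoquinone conformation and interfacial location"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining lipoquinone conformation and interfacial location}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipofold)
```

## The scientific problem

Lipoquinones — ubiquinones (UQ) and menaquinones (MK) — carry electrons and
protons through the membrane-bound electron transport system.  They consist
of a redox-active quinone headgroup and an isoprenyl tail, and although they
are usually drawn extended, their function depends on how they actually fold
and where they sit in the membrane.  Truncated analogs with two isoprene
units (UQ-2, MK-2) are experimentally tractable stand-ins for the native
UQ-10/MK-9.

Three kinds of desk-scale evidence bear on the question, and this package
implements the complete analysis chain for each:

1. **NOE calibration and conformer construction.**  2D NOESY/ROESY
   cross-peak volumes report through-space proton–proton proximity
   (roughly within 5 Å).  Volumes are standardized against a reference
   pair with known distance, binned into strong/medium/weak classes, mapped
   to distance bounds, and used as restraints for a torsion-space conformer
   search.  The key observable is the dihedral φ about the
   C2–C3–Cβ–Cγ bond (ring methyl carbon, ring chain carbon, first two
   chain carbons): φ ≈ ±90° defines a *folded* conformer.
2. **Reverse-micelle (RM) chemical shifts.**  In an AOT/isooctane RM
   (size set by w₀ = [water]/[surfactant]), the probe's ¹H shifts relative
   to the neat-organic and bulk-water endpoints locate it in the organic
   phase, the water pool, or the interface.
3. **Langmuir monolayers.**  Compression isotherms (surface pressure
   π = γ₀ − γ versus area per molecule) of pure and mixed
   phospholipid/lipoquinone films show whether the additive stays in the
   film at physiological pressure (30–35 mN/m) or is squeezed out.

Because no spectrometer or trough output is redistributable here, the
package also ships seeded generators (`simulate_peak_table()`,
`simulate_isotherm()`, `simulate_shift_table()`) that produce every input
format from known ground truth, so the whole chain is testable end to end.

## Volume → distance calibration

`normalize_volumes()` divides every volume integral by the reference-pair
volume (the quinone ring methyl H_W against the adjacent benzylic
methylene H_M/H_N, whose mean separation is ~3.5 Å in any rotamer), so
the reference maps to exactly 1.  Classes and bins follow the standard
convention:

| class  | normalized volume | distance bin |
|--------|-------------------|--------------|
| strong | > 1.5             | 1.8–3 Å      |
| medium | 0.6–1.5 (closed)  | 3–4 Å        |
| weak   | < 0.6             | 4–5 Å        |

Two closures are deliberate choices: the strong bin is floored at the van
der Waals H···H contact (1.8 Å), and the weak bin is capped at the NOE
detection range (5 Å) by default — configurable to unbounded, because
experimentally cross peaks are occasionally seen for pairs that models
place beyond 5 Å; the pipeline flags such restraint/model conflicts
(`fit_conformer()`'s violation report) rather than adjudicating them.

`ispa_distance()` is the continuous isolated-spin-pair counterpart,
r = r_ref · V^(−1/6).  The bins and the r⁻⁶ law disagree in two narrow
zones (for r_ref = 3.5: about 3.0–3.27 Å and 3.81–4.0 Å); the tests
enumerate those zones exactly rather than pretending the bins are
everywhere consistent.

**Distance convention.**  Distances between proton *groups* (methyls,
equivalent pairs) use the arithmetic mean over member-proton pairs by
default, with full r⁻⁶ pooling available as `mode = "r6"`.  The mean
convention is what anchors the calibration: the reference pair's *known*
distance, quoted as ~3.5 Å, is a mean distance.  Pooling r⁻⁶ across the
six H_W×H_MN proton pairs would put the same reference near 2.5 Å and
silently rescale the absolute 3 Å / 4 Å bins.  The synthetic generator
and the fit penalty use the same convention, so simulated volumes
round-trip through `ispa_distance()` to machine precision.

## Idealized model building and the restrained fit

`build_topology()` constructs UQ-n and MK-n with fixed ideal internal
coordinates — regular rings at 1.40 Å, C=O 1.22 Å, Csp³–Csp³ 1.53 Å,
C=C 1.34 Å, tetrahedral/trigonal angles — and expresses all flexibility
through named torsions (`phi`, allylic `chi_*`, single-bond `tauA_*` /
`tauB_*`, methyl and methoxy rotors).  Chain double bonds are fixed
E-configured.  Sub-0.1 Å geometric fidelity is irrelevant against 1 Å
wide restraint bins, which is why no force field is used: the published
workflow used MMFF94 only to regularize bond lengths, a role the fixed
ideal geometry plays here by construction.

`fit_conformer()` searches the backbone torsions only (methyl rotors stay
staggered), scoring a flat-bottom quadratic penalty on restrained group
distances plus a soft-sphere repulsion (2 Å cutoff) between heavy atoms
three or more bonds apart.  The search is multi-start Nelder–Mead with an
explicit seed; results carry the seed, the number of starts and a
per-restraint violation report, and `penalty == 0` if and only if every
restraint is satisfied in a clash-free conformer.

**Negative information.**  A monitored pair that shows *no* cross peak is
itself evidence: the pair lies beyond the detection range.
`restraints_from_table(expected_pairs = ...)` converts such absences into
lower-bound restraints (d ≥ 5 Å).  Without them, restraint sets derived
from an extended conformer would be satisfied equally well by folded
geometries, and no NOE analysis could distinguish the two.

## Conformation taxonomy

`classify_conformation()` implements the three-family scheme:

* **folded** when |φ| ∈ [60°, 120°] (the literature consensus is ~90°;
  the window is configurable);
* among folded conformers, **U-shaped** when at least one terminal methyl
  (H_Y or H_Z) sits within d_U = 6 Å (mean distance) of the ring methyl
  H_W — i.e. the tail curls back over the headgroup — otherwise
  **folded-extended**;
* everything else is **flat-extended**.

`reference_conformer()` provides one canonical member per family.  The
torsion sets were fixed once, by a grid search over clash-free backbone
torsions, to realize the geometries the families describe: the U-shaped
reference places the terminal methyls over the ring at
H_W↔H_X/H_Z/H_Y distances of about 2.4/3.6/4.6 Å, and the
folded-extended reference holds the tail beside the headgroup with a
mean H_W↔H_Y distance of ≈5.1 Å.  These conformers define the synthetic
study conditions for every recovery experiment and are not tuning knobs.

One boundary is intentionally soft: a folded-extended geometry with a
5.1 Å terminal distance falls under the 6 Å U-shape cutoff, so the two
folded subfamilies shade into each other — precisely the regime (benzene,
pyridine) where the experimental assignment is itself "open U-shaped or
folded-extended".  Tests in that regime accept either label.

## Reverse-micelle localization

`localize()` compares each probe proton's mean RM shift with the two
endpoint shifts.  With d_org and d_aq the absolute differences against the
organic and aqueous endpoints:

* **aqueous** if d_aq ≤ τ_small and d_org ≥ τ_large;
* **organic** if d_org ≤ τ_zero and d_aq ≥ τ_large;
* **interface** if τ_zero < d_org ≤ τ_small and d_aq ≥ τ_large;
* **indeterminate** otherwise, or when probe protons disagree.

Defaults τ_small = 0.03 and τ_large = 0.05 ppm make the published UQ-2
vinyl-proton table (offsets +0.01/+0.02 ppm from isooctane, −0.10/−0.09
ppm from D₂O) classify as interface.  τ_zero = 0.005 ppm is this
package's addition: shifts alone cannot separate "dissolved in the
continuous organic phase" from "at the interface" unless a genuinely zero
organic-side perturbation is distinguished from a small but systematic
one.  Grading depth *within* the interface is deliberately not attempted —
the w₀-series shifts are too small to support it.

## Langmuir isotherm workup

The workup follows trough practice: `surface_pressure()` (π = γ₀ − γ),
`average_replicates()` (linear interpolation onto a common pressure grid,
sample SD of the area reported at every 5 mN/m), `normalize_area()`
(A_N = A/x, area per phospholipid; the x⁻¹ reading is forced by the
requirement that normalized areas stay positive and comparable to the
pure film), `compression_modulus()` (Cs⁻¹ = −A·dπ/dA) and
`collapse_pressure()`.

Collapse is located at the minimum of d²A/dπ² after Savitzky–Golay
smoothing (order 2, 11-point window on a 0.25 mN/m grid — raw second
derivatives of trough data are noise-dominated).  The minimum must be
a pronounced feature (|d²A/dπ²| above a configurable threshold, default
1 Å² (mN/m)⁻²), so a featureless straight line reports no collapse.  The
low-pressure filter edge is excluded as a candidate; the high-pressure
edge is *not*, because a collapse plateau caps the pressure range and
puts the true minimum at the top of the grid by construction.

`area_expansion()` averages the normalized-vs-pure area offset over the
physiological window (30–35 mN/m), and `overlap_flag()` formalizes the
visual error-bar rule: *separated* only when the mean ± 1 SD bands are
disjoint at every 5 mN/m checkpoint in the window.  That decision rule is
a declared convention — the published comparison is visual — and is the
package's stand-in, not a community standard.

## What the generators emulate — and what they do not

`simulate_peak_table()` draws volumes ∝ d⁻⁶ from a known conformer
(ensembles pool d⁻⁶), suppresses pairs beyond the 5 Å range, and applies
mean-one multiplicative lognormal noise (NOE integrals are positive with
roughly proportional error).  `simulate_isotherm()` samples
piecewise-linear phase models — gas lift-off, liquid segments, collapse
plateau — with independent Gaussian area scatter per replicate
(`uq2_phase_model()` collapses at 21 mN/m; `dppc_phase_model()` at
70 mN/m).  `simulate_shift_table()` places RM shifts at the organic
endpoint (organic truth), at the aqueous endpoint (aqueous truth), or at
a small systematic offset from the organic endpoint (interface truth,
0.015 ppm by default, matching the order of the published offsets), plus
0.003 ppm jitter.

None of these generators model spin diffusion, mixing-time build-up,
peak overlap beyond a boolean flag, trough hysteresis, monolayer
dissolution, or temperature effects.  Passing recovery tests therefore
demonstrates that the *analysis chain* is correct and well-conditioned
under its stated error model — not that real spectra or isotherms will be
this clean.

## Numerical choices and problem sizes

* Embedding is exact natural-extension (NeRF) reconstruction from
  internal coordinates (compiled kernel, with an R reference
  implementation tested for equality); torsion assignment/measurement
  round-trips to 1e-6° on a 15° grid.
* Superposition is closed-form Kabsch (SVD with a proper-rotation
  determinant correction), cross-checked against an independent
  least-squares implementation.
* The multi-start fit uses Nelder–Mead (restart count and seed always
  recorded); ties between feasible basins are resolved by whichever basin
  the seeded starts reach first — restraint sets that genuinely admit
  several families will show it across seeds.
* Recovery experiments use 50 seeds at volume noise cv = 0.2 for the
  conformer pipeline (12 starts per fit), 50 seeds at 0.5 Å² scatter for
  collapse detection, and 100 seeded tables for localization; these sizes
  give stable pass/fail margins while keeping the default test run short.
* Degenerate inputs fail loudly: nonpositive volumes, diagonal peaks,
  missing reference pairs, lower > upper restraints, non-monotone phase
  models, disjoint replicate pressure ranges and collinear superposition
  subsets are all explicit errors with row/pair identification.

## Known limitations

* The taxonomy depends on two configurable cutoffs (folded window, d_U);
  near the boundaries the labels are genuinely soft, as they are
  experimentally.
* Binned calibration and the r⁻⁶ law disagree in two narrow distance
  zones; restraints for pairs there can be mildly inconsistent with the
  generating geometry (the fit reports the residual penalty honestly).
* The NOE model ignores spin diffusion, so long-range "anomalous" cross
  peaks can only be flagged, never explained.
* Localization grades coarse compartments only (organic / interface /
  aqueous); depth within the interface is out of reach of the shift data.
* The isotherm phase models are piecewise-linear idealizations; they are
  adequate for testing detection and normalization logic, not for
  thermodynamic analysis of mixing.
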