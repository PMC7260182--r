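---
title: "Methods: conformational energy landscapes and IR spectra of glycosyl cations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational energy landscapes and IR spectra of glycosyl cations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celiris)
```

## The problem

Glycosyl cations are the fleeting intermediates of chemical glycosylation.
After the anomeric leaving group departs, the resulting oxocarbenium ion
(C1=O5⁺ character) can be trapped intramolecularly by an acyl protecting
group elsewhere on the ring, forming a bicyclic dioxolenium ion — classical
neighboring-group participation from C-2, or long-range participation (LRP)
from C-3, C-4, or C-6. Whether that happens controls the stereochemical
outcome of the reaction. Two computational lines of evidence bear on it:

1. **Conformational energy landscape (CEL) maps** — the relative free
   energy of the cation over every accessible ring shape, drawn on the
   Cremer–Pople puckering sphere, computed separately for the acyl rotamer
   that can participate (R1, carbonyl toward C1) and the one that cannot
   (R2). If the best R1 structure lies well below the best R2 structure,
   LRP is thermodynamically favorable.
2. **Infrared ion spectra** — gas-phase action spectra of mass-selected
   cations, assigned by comparison with simulated spectra of candidate
   structures. Oxocarbenium, dioxolenium, and ring-opened ions have
   distinct diagnostic bands in the 700–1850 cm⁻¹ window.

This package implements both workflows end to end, with the expensive
electronic-structure steps behind a pluggable backend contract so that the
whole machinery runs — and is validated — at desk scale.

## Cremer–Pople puckering

`cp_coordinates()` implements the standard mean-plane construction for a
six-membered ring: positions are centered on the ring centroid, the mean
plane is fixed by the two trigonometrically weighted position sums, and the
out-of-plane displacements `z_j` (which sum to zero by construction) are
decomposed into the m = 2 pair (`q2`, `phi2`) and the alternating m = 3
amplitude `q3`. The sphere coordinates are `Q = sqrt(q2² + q3²)`,
`theta = acos(q3/Q)`, `phi = phi2`.

Two conventions are deliberate and documented rather than inherited:

* **Atom ordering** is O5 → C1 → C2 → C3 → C4 → C5 (`find_pyranose_ring()`
  orients the perceived ring this way; the anomeric carbon is recognized by
  its double bond to the ring oxygen, falling back to heavy-substituent
  count).
* **Phase** is fixed so that the ideal ⁴C₁ chair displacement pattern
  (O5, C2, C4 above the plane) gives `theta = 0`. The carbohydrate
  literature uses this orientation for D-pyranoses; the reference rings
  built by `ideal_ring_geometry()` traverse clockwise in their own plane so
  that the Cremer–Pople normal reads displacements with positive sign.

The 38 canonical conformers (2 chairs, 6 boats, 6 skew-boats, 12
half-chairs, 12 envelopes) are not hard-coded as angle tables. Their
reference positions are derived at load time by pushing each form's
idealized displacement pattern (alternating for chairs, para-pair for
boats, meta-opposed for skew-boats, adjacent-opposed for half-chairs,
single-atom for envelopes) through `cp_coordinates()` itself. This places
chairs at the poles, half-chairs at θ ≈ 50.8°, envelopes at θ ≈ 54.7°, and
boats/skew-boats alternating every 30° of φ on the equator — and guarantees
the classification (`classify_conformer()`, nearest reference by
great-circle distance) is exactly self-consistent with the forward
transform. Rings with `Q < 0.1` Å are reported `"planar"` rather than
forced onto a name; ties in the nearest-reference search (possible only
exactly midway between references) resolve to the earlier table row.

```{r pucker}
ring <- ideal_ring_geometry("4H3", amplitude = 0.55)
cp <- cp_coordinates(ring)
cp
classify_conformer(cp)$name
```

## The prefixed dihedral grid

The ring's conformational space is surveyed by constraining the three
alternating endocyclic dihedrals C1–C2–C3–C4, C3–C4–C5–O5, and C5–O5–C1–C2
on a grid from −60° to +60° in 15° steps: 9³ = 729 prefixed conformations
per acyl rotamer (`generate_grid()`), enumerated in fixed lexicographic
order. Every other internal coordinate relaxes.

`embed_constrained()` realizes one grid point as a 3D structure: the
molecule is minimized under the valence scaffold with harmonic torsion
restraints (default k = 3000 kJ/mol/rad², chosen so torsional scaffold
forces of a few kJ/mol leave sub-degree residuals) on the three ring
dihedrals plus, when an acyl ester is present, the rotamer torsion. The
constraints are *held* through the optimization — the prefixing
interpretation of the protocol — and a verification pass compares achieved
against requested dihedrals (default tolerance 1°). Because a given
dihedral triple may be unreachable from the input ring chirality, a point
that misses tolerance is retried from the geometry's reflection through
the ring mean plane, keeping the result with the smaller residual
violation.
Geometrically unsatisfiable corners of the grid (typically a few percent of
points) are returned flagged `"failed"` and become missing cells of the
map, never silent drops.

The rotamer definition needs no per-sugar hand-coding: R1 and R2 targets
are 180° apart about the ring-C–O(ester) bond, and which of the two puts
the carbonyl carbon nearer C1 — the geometric meaning of
"participation-capable" — is decided by rigid rotation and distance
measurement (`find_rotamer_torsion()`).

## Energy backends

All energies cross module boundaries in kJ/mol through one S3 contract
(name, declared capabilities, `energy`/`optimize`/`frequencies` closures).

* `toy_backend()` — an analytic surface over the puckering sphere: inverted
  Gaussian wells of chosen depth and angular width at chosen (θ, φ), plus
  an optional cosine rotamer-torsion preference. Because the landscape is a
  closed form, pipeline runs against it have exactly known outcomes; this
  is the package's primary validation instrument.
* `forcefield_backend()` — a generic valence forcefield written for this
  package: harmonic bonds and angles (equilibrium values from a small
  element-pair table), 2-/3-fold cosine torsions, and a 12-6 nonbonded term
  with 1-4 scaling, with analytic gradients throughout. Frequencies come
  from a central-difference Hessian of the analytic gradient,
  mass-weighted; intensities from a fixed bond-increment partial-charge
  dipole model (charge flux neglected). It aims at *sane, reproducible*
  geometries and energy orderings, not MMFF-class accuracy — which is all
  the surrounding pipeline logic needs, and the backend swap changes
  numbers but never the shape or completeness of any output.
* The external program boundary: `write_qc_input()` emits a Gaussian-style
  deck (route, charge/multiplicity, coordinates, ModRedundant dihedral
  constraints, PCM solvent keyword on request; byte-stable), and
  `parse_qc_output()` reads the matching log dialect, flagging imaginary
  frequencies. `write_interchange()`/`read_interchange()` define the
  neutral format — one JSON record per conformer per line — that any
  external result is converted into once; nothing downstream ever needs
  the external program. The semi-empirical screening step of the staged
  workflow is just another slot of this contract; in this package the
  valence forcefield fills it.

## Thermochemistry

`thermo_corrections()` implements rigid-rotor–harmonic-oscillator
statistics: ZPE, the thermal vibrational enthalpy, and entropy, plus
ideal-gas translational and rotational parts (1 bar, symmetry number 1 —
the cations of interest are asymmetric) when a structure is supplied. The
quasi-harmonic scheme raises frequencies below a cutoff (default
100 cm⁻¹, configurable; the entropy-interpolation alternative is noted but
not implemented) to the cutoff *for the entropy evaluation only*, so
harmonic and quasi-harmonic results coincide exactly when no mode is below
the cutoff. Two temperatures recur as defaults in the workflows: 213.15 K
(the −60 °C solution-phase glycosylation conditions, used for CEL maps)
and 298 K (gas-phase IR free energies). `boltzmann_weights()` normalizes
`exp(−ΔG/RT)` relative to the ensemble minimum and is invariant to
constant shifts.

## CEL maps

`build_map()` assigns each optimized conformer to a sphere-slice cell.
The slicing realizes "one cell per canonical conformer region": polar caps
for the chairs, a 12-cell northern and southern tier (half-chairs and
envelopes share a tier, φ bins 30° wide centered on the canonical
positions), and a 12-cell equatorial belt — 38 cells partitioning the
sphere exhaustively and disjointly. Band boundaries are the angular
midpoints between tiers. Cell energy is the minimum over members (ties to
the earliest record); duplicates within 0.1 Å heavy-atom RMSD and
0.1 kJ/mol collapse first. Energies are relative to a configurable zero —
per map by default, or a common zero across both rotamer maps of one
cation so that `compare_rotamers()` is meaningful; it refuses maps with
inconsistent references.

`find_local_minima()` returns occupied cells no higher than any occupied
neighbor (φ periodic; caps neighbor their whole adjacent tier); on a flat
surface every occupied cell qualifies, a documented degenerate behavior.
`compare_rotamers()` reports ΔΔG = G(R1) − G(R2) in kcal/mol with a
significance threshold (default 0.5 kcal/mol) below which the verdict is
`"indeterminate"`. `export_heatmap()` writes a fixed-format CSV
(byte-stable across re-exports) and a figure shaded in steps of the
contour interval, default 0.5 kcal/mol.

```{r celmap}
canon <- canonical_conformers()
well <- canon[canon$name == "1C4", ]
tb <- toy_backend(data.frame(theta = well$theta_ref, phi = well$phi_ref,
                             depth = 25, width = 25))
run <- run_grid(ideal_ring_geometry("4C1", 0.55), grid_spec(-60, 60, 30),
                rotamer = "R1", backend = tb)
map <- build_map(run$records)
head(find_local_minima(map), 3)
```

## The IR pipeline

`run_ir_pipeline()` chains the staged workflow with its stated defaults,
all overridable through `ir_config()` (or a YAML file):

| stage | parameter | default |
|---|---|---|
| conformer search | embeddings | 500 |
| diversity selection | max kept (max–min heavy-atom RMSD, lowest-energy first) | 40 |
| energy filter | window above minimum | 40 kJ/mol (80 for pyranosyl cations) |
| frequency scaling | factor | 0.975 |
| broadening | Gaussian width | 20 cm⁻¹, read as FWHM |
| ensemble | temperature | 298 K |
| trace grid | spacing / range | 1 cm⁻¹ over 700–1850 cm⁻¹ |

The conformer search embeds random distance matrices drawn within
graph-derived bounds (exact 1-2 and 1-3 distances, van-der-Waals lower and
bonded-path upper bounds elsewhere) by metric-matrix projection, then
minimizes each embedding with the forcefield. The whole pipeline is
deterministic under the configuration seed. Saddle points (imaginary
modes) are excluded from the ensemble, and stage counts are monotonically
non-increasing by construction.

The "20 cm⁻¹ Gaussian broadening" is interpreted as FWHM — the common
convention in the ion-spectroscopy literature — with a switch
(`width_is_fwhm = FALSE`) because the underlying protocol does not say.
Kernels are unit-area, so integrated intensity is conserved up to grid
truncation.

`match_score()` is a documented stand-in for the qualitative "best match"
judgement of spectral assignment: cosine similarity of max-normalized
traces on a common 1 cm⁻¹ grid (Pearson correlation available). It is
symmetric and invariant to uniform intensity scaling. Mixture analyses use
`ensemble_spectrum()` with explicit fractions.

`classify_ion_type()` encodes the diagnostic-band logic: oxocarbenium =
peak near 1600 cm⁻¹ (C1=O5⁺ stretch) **and** near 1800 cm⁻¹ (intact
acetyl C=O) **and** no 1550 cm⁻¹ band; dioxolenium = 1550 (O–C=O⁺
stretch) **and** 1500 (bend) **and** no 1800; ring-opened = 1550 **and** a
1730–1790 cm⁻¹ carbonyl. Rules are evaluated in the order ring-opened,
oxocarbenium, dioxolenium (the ring-opened signature is a superset of the
dioxolenium one), anything else is `"mixed/indeterminate"`. Windows
(±25–30 cm⁻¹) and the peak threshold (local maxima above 5% of the trace
maximum) are configurable.

```{r classify}
trace <- broaden(spectrum_ir(c(1550, 1500, 1790), c(1, 0.8, 0.9),
                             kind = "lines"), width = 20)
classify_ion_type(trace)$label
```

## What the surrogate backends do and do not show

The toy and forcefield backends let every structural, combinatorial, and
spectral stage run under exactly known or cheaply reproducible conditions:
grid completeness, constraint satisfaction, sphere partitioning, planted
minimum recovery, stage counts, weighting, broadening and classification
algebra. They do **not** reproduce quantum-chemical energetics: the valence
forcefield's relative conformer energies and normal-mode frequencies are
qualitative, its intensities come from fixed charges, and therefore no
number computed here should be compared against published DFT relative
energies or experimental band positions for real glycosyl cations. For
production work the same pipeline consumes external-program results
through the interchange boundary.

Problem sizes in the bundled examples and checks were chosen to exercise
every code path at interactive speed: the full 729-point grid on the bare
ring fixture, coarser 27-point grids where only comparison logic is under
study, and the full 500-conformer search on the 15-atom tetrahydropyranyl
oxocarbenium ion, the smallest pyranosyl-cation model.

## Known limitations

* The distance-geometry embedder does not enforce chirality or planarity
  constraints; for the small symmetric cations used here that is
  immaterial, but stereocenter-rich substrates would need the external
  backend's optimizer to clean up inverted centers.
* The valence forcefield has no electrostatic energy term and generic
  torsion barriers; anomeric and gauche effects central to real sugar
  conformational preferences are absent by design.
* Half-chair and envelope tiers share map cells (the tier θ values differ
  by only ~4°); the canonical *label* of a cell is still unique, and the
  classification itself distinguishes all 38 forms.
* `thermo_corrections()` treats all modes as harmonic oscillators apart
  from the quasi-harmonic raising; hindered rotors and anharmonicity are
  out of scope.
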