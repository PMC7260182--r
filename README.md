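# celiris

Conformational energy landscapes (CEL) and simulated infrared ion spectra
of glycosyl cations, in R.

Glycosyl cations — the oxocarbenium-ion intermediates of chemical
glycosylation — can be stabilized when an acyl protecting group at C-2
(neighboring-group participation) or at C-3/C-4/C-6 (long-range
participation, LRP) bridges to the cationic center and forms a bicyclic
dioxolenium ion. Two computational workflows probe this, and this package
implements both as reusable, tested components for computational
carbohydrate chemists:

1. **CEL mapping.** The ring's conformational space is surveyed by fixing
   the three alternating endocyclic dihedrals (C1–C2–C3–C4, C3–C4–C5–O5,
   C5–O5–C1–C2) on a −60°…+60° grid in 15° steps — 9³ = 729 prefixed
   conformations per acyl rotamer — relaxing everything else, and placing
   each optimized structure on the Cremer–Pople puckering sphere
   (amplitude Q, angles θ, φ; poles ⁴C₁/¹C₄, equator boats/skew-boats).
   Relative Gibbs energies are binned into 38 sphere-slice cells (one per
   canonical conformer region), local minima located, and the two acyl
   rotamer maps (R1 = carbonyl toward C1, participation-capable; R2 =
   away) compared: ΔΔG = G(R1) − G(R2) below a −0.5 kcal/mol threshold is
   called LRP-favorable.
2. **IR spectrum simulation.** From a SMILES string: 500 distance-geometry
   conformers minimized with a classical forcefield, at most 40 kept by
   max–min RMSD diversity selection, an energy window of 40 kJ/mol
   (80 kJ/mol for pyranosyl cations), harmonic frequencies scaled by
   0.975, 20 cm⁻¹ FWHM Gaussian broadening on a 700–1850 cm⁻¹ grid,
   Boltzmann ensemble averaging at 298 K, cosine-similarity matching
   against experimental traces, and diagnostic-band classification:
   oxocarbenium (≈1600 cm⁻¹ C1=O5⁺ stretch + ≈1800 cm⁻¹ intact ester),
   dioxolenium (≈1550 stretch + ≈1500 bend, no 1800), ring-opened
   (≈1550 + 1730–1790 cm⁻¹ carbonyl).

Electronic-structure energies and frequencies enter through a pluggable
backend contract: an analytic toy surface with wells planted at known
sphere positions (exact expected outcomes for validation), a generic
valence forcefield (all stages run in seconds), and a file adapter for an
external quantum-chemistry program (Gaussian-style decks and logs, plus a
neutral one-JSON-record-per-line interchange format).

## Worked example

Plant two wells on the puckering sphere — a 25 kJ/mol well at the ⁴C₁
pole and an 18 kJ/mol well at the ¹S₅ skew-boat — run the full 729-point
constrained grid on an ideal pyranose-like ring, and map it:

```r
library(celiris)
canon <- canonical_conformers()
wells <- canon[canon$name %in% c("4C1", "1S5"), ]
tb <- toy_backend(data.frame(theta = wells$theta_ref, phi = wells$phi_ref,
                             depth = c(25, 18), width = 25))
run <- run_grid(ideal_ring_geometry("4C1", 0.55), grid_spec(-60, 60, 15),
                rotamer = "R1", backend = tb)
map <- build_map(run$records)
map
#> CEL map (R1): 38/38 cells occupied, 361 conformers, min cell 4C1
head(find_local_minima(map), 2)
#>   cell label dG_kjmol  dG_kcal record
#> 1  4C1   4C1 0.000000 0.000000    317
#> 2  1S5   1S5 6.643218 1.587767    143
```

Both planted minima are recovered: the global minimum cell is ⁴C₁ at
0 kJ/mol, and the second local minimum is ¹S₅ at 6.6 kJ/mol — the 7 kJ/mol
depth difference of the two wells, up to the grid's angular resolution.
`export_heatmap(map, "map.csv", "map.png")` writes the table and the
0.5 kcal/mol-contoured figure.

Classifying a synthetic oxocarbenium-like trace:

```r
trace <- broaden(spectrum_ir(c(1600, 1800), c(1, 0.7), kind = "lines"),
                 width = 20)
classify_ion_type(trace)
#> ion assignment: oxocarbenium
#>   oxocarbenium_1600      [1575-1625] peak at 1600
#>   ester_1800             [1770-1830] peak at 1800
#>   dioxolenium_1550       [1525-1575] -
#>   dioxolenium_1500       [1475-1525] -
#>   ring_opened_carbonyl   [1730-1790] -
```

The full IR pipeline on the smallest pyranosyl-cation model:

```r
res <- run_ir_pipeline("C1=[O+]CCCC1", ir_config(seed = 1), pyranosyl = TRUE)
res$stages      # generated 500 -> selected <= 40 -> filtered -> minima
res$spectrum    # Boltzmann-weighted composite trace, 700-1850 cm^-1
```

See `vignettes/celiris-methods.Rmd` for the model conventions (atom
ordering, Cremer–Pople phase, slicing scheme), every tunable parameter,
and what the desk-scale backends do and do not validate.

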