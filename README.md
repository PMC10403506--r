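# llcchar

Structural and functional characterisation of lyotropic liquid-crystalline
(LLC) nanoparticles — cubosomes and hexosomes — for soft-matter and
drug-delivery researchers who need to turn raw characterisation data
(1D SAXS profiles, periodic electron-micrograph regions, spectroscopic
assay tables, annotated confocal images) into phase assignments, lattice
parameters, channel geometries, encapsulation figures and fusion
statistics.

## What it computes

**SAXS indexing.** A Bragg peak at momentum transfer *q* probes the plane
spacing *d* = 2π/*q*. Allowed reflections of each mesophase fall at
characteristic ratios — √2:√3:√4:√6:√8:√9 for the double-diamond cubic
Pn3m, √2:√4:√6 for the primitive cubic Im3m, 1:√3:√4 for the inverse
hexagonal p6mm — and the lattice parameter follows

    a_cubic = 2π √(h² + k² + l²) / q_hkl
    a_hex   = 4π √(h² + hk + k²) / (√3 q_hk)

The package detects peaks over a power-law baseline, ranks candidate
phases by greedy ratio matching, fits *a* by regressing *q* on the spacing
factor (a near-zero free intercept is the quality check for a correct
assignment), and derives water-channel radii: r_w = 0.391·a − l_c (Pn3m),
0.305·a − l_c (Im3m), a/2 − l_min (hexagonal).

**Micrograph lattices.** 2D power spectra of periodic image regions give
Friedel spot pairs at radius 1/d; square ([001] cubic) and hexagonal
([111] cubic or tubule-axis p6mm) patterns map d to *a*, with the √2:√4
secondary-ring test identifying the primitive cubic. A grey-scale
line-profile route cross-checks the spacing in real space.

**Assays.** Linear standard curves with dynamic-range flags; loading
efficiency 100·(C₀ − C_f)/C₀ from pellet-derived unencapsulated dye;
release efficiency 100·(F(t) − F₀)/(F_triton − F₀) for self-quenching
dyes normalised to surfactant lysis.

**GUV fusion.** The payload-delivery statistic ΔI = mean(lumen disc) −
mean(background annulus) per annotated vesicle; strictly positive ΔI
scores a delivery event; cohorts aggregate into histograms with per-group
delivered fractions.

**Synthetic data.** Every input has a seeded generator with attached
ground truth (exact peak centres, spacings, intensity means), so the whole
pipeline is testable without instrument data.

## Worked example

```r
library(llcchar)
prof <- gen_saxs_profile("Pn3m", a = 70.7, noise_sd = 0.05, seed = 7)
peaks <- detect_peaks(prof)
ranking <- assign_phase(peaks)
ranking
#> <phase_ranking> top: Pn3m
#>           phase n_matched rms_ratio_residual n_skipped n_candidate_reflections
#> 1          Pn3m         6       0.0005673301         0                       8
#> 2          Im3m         4       0.0004736581         0                       8
#> 3 HexagonalP6mm         3       0.0004588716         0                       8
fit <- fit_lattice(ranking$assignments[[ranking$top]])
fit
#> <lattice_fit> Pn3m: a = 70.65 A (6 peaks)
#>   intercept -0.00014 1/A (QC pass), R^2 = 1.000000
water_channel_radius(ranking$top, fit$a, lipid_chain_length("phytantriol"))
#> <channel_geometry> Pn3m: a = 70.65 A, l_c = 13.0 A, r_w = 14.62 A
```

All six generated reflections are matched by Pn3m with no skipped orders
(the rival cubics only match subsets), the fitted lattice parameter lands
within 0.1% of the generating 70.7 Å, the regression intercept is two
orders of magnitude inside the 0.005 Å⁻¹ quality threshold, and the
phytantriol chain length (13 Å) turns the lattice parameter into a
~14.6 Å water-channel radius.

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the full study
on synthetic inputs and write tables under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate_inputs.R` | profiles per composition, flow regimes |
| `02_saxs_indexing.R` | peak detection → phase → lattice → channels |
| `03_micrograph_fft.R` | spectral + line-profile spacings vs SAXS |
| `04_assays.R` | standard curve, loading and release efficiencies |
| `05_fusion.R` | 64-GUV ΔI cohort, histogram, delivered fractions |

Run them in order from the repository root: `Rscript analysis/01_simulate_inputs.R` etc.

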