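---
title: "Characterising liquid-crystalline nanoparticles: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising liquid-crystalline nanoparticles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(llcchar)
```

## The scientific problem

Cubosomes and hexosomes are colloidal dispersions of inverse lipid
mesophases: a bilayer draped over a triply periodic minimal surface (the
double-diamond Pn3m or primitive Im3m cubic phases), or hexagonally packed
inverse lipid tubules (plane group p6mm). Their internal symmetry governs
cargo capacity and fusogenic behaviour, so characterising it — which space
group, at what lattice parameter, with what water-channel size — is the
central analytical task after synthesis. `llcchar` implements that workflow
end to end on top of seeded synthetic data with known ground truth: SAXS
Bragg-peak indexing, spectral analysis of periodic micrograph-like images,
dye loading/release assays, and the GUV payload-delivery statistic.

## SAXS indexing

### Model

A Bragg peak at momentum transfer $q$ corresponds to the interplanar
spacing $d = 2\pi/q$. For a cubic space group the allowed reflections obey

$$a_\text{cubic} = \frac{2\pi\sqrt{h^2+k^2+l^2}}{q_{hkl}},$$

and for the 2D hexagonal phase

$$a_\text{hex} = \frac{4\pi\sqrt{h^2+hk+k^2}}{\sqrt{3}\,q_{hk}},$$

so each phase produces a characteristic sequence of peak-position ratios:
$\sqrt2:\sqrt3:\sqrt4:\sqrt6:\sqrt8:\sqrt9$ for Pn3m,
$\sqrt2:\sqrt4:\sqrt6$ for Im3m, $1:\sqrt3:\sqrt4$ for p6mm. Note the sign
in the hexagonal index form: with 2D indices written as positive $(h,k)$
the invariant is $h^2+hk+k^2$ — that is what yields $1:\sqrt3:\sqrt4$ for
(10), (11), (20); the variant with $-hk$ corresponds to the alternative
Miller–Bravais sign convention and does not reproduce the sequence with
all-positive indices.

Phase assignment normalises observed positions by an anchor peak and
greedily matches successive ratios against each candidate sequence.
The anchor is the first *matched* peak: the first few observed peaks are
each tried as the anchor and the best-scoring alignment kept, which makes
the assignment robust to a spurious low-$q$ detection. Expected reflections
may be skipped (weak orders are often unobservable) and observed peaks may
go unmatched (spurious).

### Tunable parameters

* `ratio_tolerance` (default **0.02**, relative): the per-peak deviation
  allowed when matching ratios. 2% separates $\sqrt6 = 2.449$ from
  $\sqrt8 = 2.828$ comfortably at realistic peak precision; widening much
  beyond 5% makes Pn3m and Im3m collide.
* `min_peaks` (default **3**): the smallest indexed set treated as a
  confident assignment — the smallest set the workflow itself relies on
  (Im3m and p6mm show three accessible reflections). Fewer matches flag
  the ranking as ambiguous rather than raising an error.
* `intercept_qc` (default **0.005 Å⁻¹**): the lattice fit regresses $q$ on
  the spacing factor with a *free* intercept; a correct indexing puts the
  intercept near zero, so its magnitude is reported as quality control
  instead of being forced away. Deliberate mis-indexing (mapping the $i$-th
  peak to the $i$-th reflection of the wrong group, `force_index()`)
  violates this threshold on the same peaks that pass it under the correct
  group — greedy matching alone cannot show this, because the wrong cubic
  group can match an exact *subset* of the other's reflections with zero
  residual.
* Ranking ties break by: more matched peaks, lower RMS ratio residual
  (compared at 9 significant digits, because different groups share exact
  ratio values like $\sqrt6/\sqrt2 = \sqrt3$ up to floating rounding),
  then fewest skipped reflections — the simpler indexing wins. This is what
  lets three peaks at $\sqrt2:\sqrt4:\sqrt6$ resolve to Im3m rather than to
  a Pn3m indexing that skips $\sqrt3$.

### Peak detection numerics

Detection subtracts a power-law-plus-constant baseline $Aq^{-p}+c$ — the
typical small-angle background — fitted in log space to per-bin low-quantile
anchor points so that narrow peaks do not pull it up, with a final
recalibration by a low quantile of intensity/baseline ratios (for
signal-proportional noise the anchor quantile biases the fit by a constant
factor, which the ratio quantile estimates). Candidate maxima on the lightly
smoothed residual must clear two thresholds: a fraction `min_prominence`
(default 0.05) of the maximum baseline-subtracted intensity, and
`snr_min` (default 5) multiples of the *local* noise level (rolling MAD of
the smoothing residual). The second guard matters because with noise
proportional to signal, the absolute noise near the low-$q$ baseline can
dwarf the noise near high-$q$ peaks. Peak centres are refined by an
intensity-weighted centroid over the upper half of each peak, which
averages point noise that a three-point parabola cannot.

### Water channels

From the fitted lattice parameter and an approximate liquid-disordered
chain length ($l_c \approx 18$ Å for monoolein, $\approx 13$ Å for
phytantriol), the aqueous channel radii follow $r_w = 0.391a - l_c$ (Pn3m),
$r_w = 0.305a - l_c$ (Im3m) and $r_w = a/2 - l_\text{min}$ with
$l_\text{min}=l_c$ (hexagonal close-packed tubules). A negative radius is
reported with a warning — it signals an implausible $a$/$l_c$ pairing
rather than a computational failure.

```{r saxs-example}
prof <- gen_saxs_profile("Pn3m", a = 70.7, noise_sd = 0.05, seed = 7)
peaks <- detect_peaks(prof)
ranking <- assign_phase(peaks)
fit <- fit_lattice(ranking$assignments[[ranking$top]])
fit
water_channel_radius(ranking$top, fit$a, lipid_chain_length("phytantriol"))
```

## Micrograph lattice estimation

The 2D power spectrum (Hann-windowed, zero-frequency centred, axes in
cycles/Å) of a projected lattice shows spot pairs at radius $1/d$. A cubic
particle viewed along [001] gives four first-order {110} spots at 90°; a
[111] view, or the inverse-hexagonal phase down its tubule axis, gives six
spots at 60°. The two cubic views are distinguished by the secondary
reflection ring: a hexagonal pattern with a second ring at $\sqrt2$ times
the first-order radius (the $\sqrt2{:}\sqrt4$ signature) identifies the
primitive cubic, for which $a = d_{110}\sqrt2$; a plain hexagonal pattern
maps to p6mm with $a = 2d_{10}/\sqrt3$.

Numerical choices:

* **Window**: Hann by default; without it, edge discontinuities streak
  through the spectrum and masquerade as spots.
* **Central exclusion**: radii below two reciprocal pixels
  ($2/(\text{side}\times\text{pixel size})$) are ignored, removing DC and
  low-frequency background.
* **Noise rejection**: candidate maxima must exceed both a fraction
  (default 0.1) of the strongest off-centre magnitude and 10× the median
  off-centre magnitude. The absolute floor is what makes a white-noise
  spectrum return *no* spots: the maxima of Rayleigh-distributed noise
  magnitudes sit only 3–4× above the median, while a coherent lattice spot
  sits orders of magnitude higher. Friedel pairing (partner at angle
  $+\pi$ within 5° and 5% radius) then discards whatever unpaired maxima
  survive.
* **Sub-pixel refinement**: spot positions are refined by a 3×3 magnitude
  centroid; recovered spacings are accurate to well within one
  reciprocal-space pixel.
* The real-space cross-check interpolates a grey-scale profile along a
  user-chosen segment and takes the period from the first autocorrelation
  peak. On a square pattern profiled along a wave normal this reproduces
  $d$ directly; on a three-wave hexagonal pattern the profile direction
  determines which super-period is seen, so the spectral route is the
  primary estimator and the line profile a visual/diagnostic one.

Recovery experiments size the image to the spacing under test: side =
smallest power of two at or above $8d/\text{pixel size}$ (at least 128),
so every image contains at least eight periods and the first-order spot
clears the exclusion disc across the whole tested range
($d$ 20–120 Å, 1–4 Å/px).

```{r fft-example}
img <- gen_lattice_image("hexagonal", d = 105, pixel_size = 4, size = 256,
                         harmonics = data.frame(ratio = sqrt(2),
                                                amplitude = 0.5),
                         seed = 7)
lattice_from_spots(detect_spots(power_spectrum(img)), "hexagonal")
```

## Encapsulation assays

Standard curves are ordinary least-squares lines; inversion flags, rather
than refuses, responses outside the fitted dynamic range (a hexosome-like
sample whose signal falls below the curve still yields a number plus an
`out_of_range` flag). Loading efficiency is
$100\,(C_0 - C_f)/C_0$ with $C_f$ the unencapsulated pellet-derived
concentration — the fraction of dye retained by the particles. (The
textbook-style expression "$1 - ((C_0-C_f)/C_0 \times 100\%)$" sometimes
quoted for this assay is dimensionally inconsistent; the implemented form
is the one consistent with pellet-derived $C_f$ and with efficiencies in
the tens of percent.) Release efficiency for a self-quenching dye is
$100\,(F(t)-F_0)/(F_\text{triton}-F_0)$, linearly interpolated in time and
clamped to $[0,100]$; it presumes fluorescence linear in released dye,
i.e. the dilute post-release regime. No release metric is defined for a
non-self-quenching dye such as curcumin — lysis produces no spectroscopic
step to normalise against — so none is computed.

## GUV delivery statistic

For an annotated vesicle (centre, radius), `delta_i()` averages the image
over an inner disc of 0.5 radii — inside the lumen, clear of the membrane
ring — and over a background annulus at 1.2–1.5 radii, and reports the
difference. The statistic is invariant under additive intensity offsets
and scales linearly under gain changes, so the delivered/not-delivered
decision (strictly positive difference, threshold 0 by default) is
insensitive to detector settings. Region means are used rather than
line-profile plateaus; the profile route (`intensity_profile()`) is kept
for visual parity with confocal cross-sections. Histograms use
Freedman–Diaconis binning on the pooled values unless a width is given.

The region defaults are a design choice the underlying assay does not pin
down: published analyses rarely state their integration regions. The inner
fraction of 0.5 trades lumen coverage against membrane contamination;
pushing it past ~0.8 lets the ring's point-spread tail bias the inner mean.

## What the synthetic data does and does not emulate

The generators reproduce the *geometry* of each measurement with attached
ground truth: Gaussian Bragg peaks at exact reflection positions over an
$Aq^{-2}+c$ baseline with signal-proportional noise; plane-wave lattice
images for square/hexagonal projections with optional harmonic rings;
disc-plus-ring vesicle images; linear standard curves; first-order release
kinetics with a surfactant step. Default study conditions: six Pn3m,
three Im3m and three p6mm reflections (the experimentally accessible
sets), peak width $\sigma_q = 0.002$ Å⁻¹, profile SNR 20 by default with
recovery suites run at SNR 10, image noise at SNR 5, and a 64-vesicle
fusion cohort split into two size classes.

They do **not** emulate: form-factor modulation of peak intensities,
instrument smearing, detector point-spread or CTF effects, membrane
point-spread bleed-through, photobleaching, or self-quenching
nonlinearity. Passing recovery tests therefore demonstrates the
correctness of the inference pipeline under controlled conditions, not
robustness to every instrumental artefact of real beamline or microscope
data.

Generators take mandatory seeds, restore the caller's RNG state, refuse
sub-Nyquist spacings and out-of-window reflections, and are bit-reproducible.

## Problem sizes

The shipped test and analysis runs use 100 seeded profiles per phase for
phase-recovery statistics, 100 lattice-image trials for spacing recovery,
20-seed nulls for the white-noise check, and the 64-vesicle cohort — sizes
at which the binomial pass criteria (99% and 95%) are meaningful while the
whole suite completes in well under a minute per module.

## Known limitations

* Phase candidates cover Pn3m, Im3m, Ia3d, p6mm and lamellar stacks;
  discrimination relies on peak *positions* only, so a candidate set whose
  ratio sequences overlap on the observed window (e.g. two peaks only)
  is reported ambiguous rather than resolved.
* The hexosome literature value pair ($a = 50$ Å, $d_{10} = 42.5$ Å) is
  mutually inconsistent with $d_{10} = a\sqrt3/2 = 43.3$ Å; both mapping
  directions are implemented and neither is treated as an exact
  cross-check of the other.
* Spectral spot detection assumes a mostly-periodic region of interest;
  there is no particle segmentation, and vesicle-vs-particle counting is a
  manual tally (`tally_particle_classes()`).
* `read_micrograph()` averages multi-channel images to grayscale; channel
  selection belongs upstream.
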