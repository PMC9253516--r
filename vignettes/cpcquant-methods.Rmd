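---
title: "Models and methods behind cpcquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cpcquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpcquant)
```

cpcquant bundles the quantitative analyses used to characterise the
interaction between the chromosomal passenger complex (CPC) and Shugoshin 1
(Sgo1): in-vitro binding thermodynamics by isothermal titration calorimetry
(ITC) and mass photometry, and in-cell readouts — centromere marker
abundance, marker pool geometry across kinetochore pairs, tethering
recruitment, and phenotype statistics. This vignette explains each model,
its assumptions, the tunable parameters, and the design decisions taken
where the underlying conventions are genuinely open.

## The 1:1 binding isotherm

An ITC experiment titrates a syringe species X (concentration
`syringe_conc_uM`) into a cell of analyte M (`cell_conc_uM`, volume
`cell_volume_ul`, default 200 µl) in an ordered series of injections
(default one 0.5-µl pre-injection plus fifteen 2.5-µl aliquots). The
perfusion cell overflows: each injection displaces cell content, so after a
cumulative injected volume $V$ the total concentrations are

$$M = M_0\,\frac{1 - V/2V_0}{1 + V/2V_0}, \qquad
  X = X_{syr}\,\frac{V/V_0}{1 + V/2V_0}.$$

These rational displacement factors are the form used by the classic
instrument-vendor fitting software; an exponential-dilution variant exists
in the literature but changes fitted constants by far less than typical
measurement noise at these fill fractions, and is not implemented. With a
single class of $N$ equivalent sites per analyte molecule, the complex
concentration solves the quadratic

$$[MX] = \tfrac12\left[(NM + X + K_D) - \sqrt{(NM + X + K_D)^2 - 4NMX}\right],$$

the cell heat content is $Q = [MX]\,\Delta H\,V_0$, and the measured heat of
injection $i$ corrects for the displaced aliquot at the mean of the
before/after compositions:

$$\Delta Q_i = Q_i - Q_{i-1} + \frac{v_i}{V_0}\,\frac{Q_i + Q_{i-1}}{2},$$

normalized per mole of titrant injected. The heat of dilution is modelled as
a constant offset per mole injected and fitted alongside the binding
parameters; subtracting a measured blank titration is supported simply by
supplying pre-corrected heats through `read_isotherm_csv()`. Under this
model the summed raw heats conserve the total binding enthalpy
$N M_0 V_0 \Delta H$ up to the displaced fraction — within 1 % when the
injected volume is a few percent of the cell, which the test suite checks
against a mole-tracking oracle.

**Fitting.** `fit_isotherm()` minimises squared residuals over
$(N, \log_{10} K_D, \Delta H, \text{offset})$ with Levenberg–Marquardt
(damped least squares). Because the isotherm is nearly flat in $K_D$ away
from the transition, the optimiser multi-starts from a coarse $K_D$ grid
($10^{-11}$–$10^{-4}$ M, one start per decade) with data-driven initial
values for the other three parameters (offset from the saturated tail,
$\Delta H$ from the initial plateau, $N$ from the mid-transition molar
ratio); the best deviance wins. The procedure uses no random numbers and is
fully deterministic. Standard errors are asymptotic (from the Jacobian at
the optimum; $K_D$ by the delta method on the log scale) and will not match
every instrument vendor's reported ± values exactly, which is expected —
the point estimates are what round-trip.

Honesty of the `converged` flag: a fit is only declared converged when the
optimiser stopped cleanly *and* the fitted transition amplitude
$|\Delta H|$ exceeds three residual standard deviations — an all-zero or
flat isotherm yields `converged = FALSE` rather than silent nonsense. A
Wiseman $c = N\,[\text{analyte}]/K_D$ outside $[1, 1000]$ is recorded as a
warning in the result: the data then poorly constrain $K_D$ regardless of
optimiser quality.

The first injection is excluded from fitting by default
(`exclude_first = TRUE`): the customary small first aliquot exchanges
material across the syringe tip during equilibration and its heat is
unreliable. This is a convention, not a fact about any particular dataset,
and is controllable.

Thermodynamic decomposition uses
$\Delta G = RT\ln K_D$ with $R = 1.98720425\times10^{-3}$ kcal mol⁻¹ K⁻¹
and $-T\Delta S = \Delta G - \Delta H$; the identity
$\Delta G = \Delta H + (-T\Delta S)$ holds to numerical precision for every
fit object.

## Synthetic microscopy scenes

`image_scene()`/`generate_cell_image()` render centromere and kinetochore
foci as isotropic 2-D Gaussians (peak amplitude per channel, common width
`sigma_um`, default 0.15 µm) on a constant per-channel background, with
additive Gaussian read noise and optional Poisson shot noise. Real
point-spread functions are Airy-like and mildly anisotropic; the Gaussian
choice is deliberate because it makes every downstream oracle analytic
(peak values, integrated intensities, profile FWHMs). The default pixel
size, 0.0645 µm, corresponds to a 6.45-µm camera pixel behind a 100×
objective — a common wide-field configuration; it is a convention of the
generator, not a measured property of any instrument.

`generate_spread_image()` turns each anchor spot into a kinetochore pair:
two ACA foci separated by `inter_kt_sep_um` (must be ≤ 1.5 µm, the
downstream pairing cap) along a per-pair axis (seeded random orientation by
default). The marker channel follows the anchor's `pool_model`:

* `inner_only` — one Gaussian at the pair midpoint (single
  inner-centromere pool);
* `dual_pool` — two Gaussians flanking the midpoint at ±80 % of the ACA
  half-separation (kinetochore-proximal pools; the fraction is
  configurable);
* `both` — all three.

Pool Gaussians are rendered with equal peak heights. The realized truth
table carries `pair_id` only on the two sister ACA foci — marker pool
Gaussians are signal structure, not kinetochores — and each pair row stores
the analytic FWHM of its marker profile (outermost half-maximum crossings
of the noiseless profile on a dense grid), the ground truth for the
FWHM-based pool discrimination.

What the generator does **not** emulate: 3-D stacks and out-of-focus light,
deconvolution artefacts, chromatic shift, photobleaching, cell-to-cell
background variation, and clustered/overlapping centromeres. Passing tests
therefore demonstrate that the measurement chain is unbiased and correctly
calibrated on resolvable Gaussian foci — not that detection is robust to
every pathology of real imaging.

Mass-photometry events are drawn from a seeded Gaussian mixture
(`mass_mixture()`), emulating per-particle mass lists from a cross-linked
sample; instrument-specific mass calibration error is not modelled.

## Centromere ring quantification

Detection operates on the ACA reference channel: difference-of-Gaussians
band-pass (σ = 1 and 3 px by default), robust threshold at
median + 5·MAD of the enhanced image, connected components within an area
range, intensity-weighted sub-pixel centroids. The centromere mask is then
an Otsu threshold inside a 9×9-px window around each centroid (an absolute
threshold can be supplied); the marker readout is the mean over a
3-pixel-wide ring — the morphological dilation of the mask minus the mask —
minus the mean over a cytoplasmic background region. When no region is
supplied the package samples the modal-intensity plateau of the marker
image, which in these scenes is cytoplasm; a manually drawn region is
always accepted, mirroring how such measurements are made interactively.

Conventions worth stating: rings clipped by the image border are flagged
and excluded by default; negative corrected intensities are retained but
flagged and left out of normalization means; ring values are averaged per
centromere and then per cell (pooling all ring pixels across a cell is the
other defensible convention and gives nearly identical means on these
scenes). `normalize_condition()` divides by the mean corrected intensity of
the reference condition, so the reference mean is exactly 1. Tethering
recruitment uses the focus mask itself (not a ring) on both channels and
reports marker/GFP after per-channel background correction, flagging
non-positive GFP.

## Kinetochore pairing and FWHM

`assign_pairs()` implements mutual-nearest-neighbour matching with a
1.5-µm cap: two centroids pair exactly when each is the other's nearest
neighbour. This is local, parameter-free beyond the cap, and deterministic;
input order cannot matter because points are canonically sorted first, and
exact distance ties resolve by lexicographic coordinate order. A greedy
global matching would differ only on pathological configurations; the test
suite checks equivalence with a brute-force oracle on a thousand random
point sets.

Profiles are sampled every half pixel (Nyquist of the sampled grid) by
bilinear interpolation along the pair axis over a 2-µm window centred on
the midpoint, and min-max normalized per profile (normalization happens
before any averaging across pairs; the other order changes only display,
not FWHM). The FWHM half level is $(\max + \text{baseline})/2$ with the
baseline at the window minimum — the window is short enough that its
minimum tracks the local background. Crossings are located by linear
interpolation; the width spans the *outermost* left and right crossings.
For a single Gaussian pool this is the textbook
$2\sqrt{2\ln 2}\,\sigma$; for resolved dual pools at ±0.4 µm it is
≈ 0.8 µm + 2.3548 σ, so breadth is monotone in pool separation — the
property that makes FWHM a discriminator between inner-centromere and
kinetochore-proximal marker distributions. Profiles whose window leaves the
image, or that are flat to within float precision, are flagged and excluded
rather than silently measured.

## Mass accounting and peak calling

`complex_mass()` is exact arithmetic over stated stoichiometries.
`kde_peaks()` uses a Gaussian KDE (Silverman bandwidth by default — the
original instrument software's setting is unknowable, and Silverman is the
neutral choice), calls local maxima above 5 % of the peak density, and
summarises each peak as mean ± SD of the events within ±2 bandwidths. The
reported SD is therefore the local population spread around the peak, not a
fitted Gaussian width. `assign_species()` matches peaks to candidate
compositions within `tol_sd` peak-SDs, breaking distance ties toward the
smaller calculated mass and leaving unmatched peaks explicitly unassigned.

## Group statistics

Kruskal–Wallis H (with tie correction) is delegated to
`stats::kruskal.test()`; Dunn's post hoc z statistics are computed
in-package from the joint ranks with the standard tie-corrected variance,
and adjusted by Holm's method by default — the unnamed "multiple
comparisons" adjustment in common practice varies, and Holm dominates
Bonferroni uniformly while controlling the same family-wise error (both
Bonferroni and Šidák are selectable). The all-tied degenerate table returns
H = 0, p = 1 rather than NaN. Dunnett's many-to-one comparisons ride on
`multcomp::glht()` over `stats::aov()`; χ² rate tests are Pearson without
continuity correction (so small-table hand calculations match exactly);
alignment phenotypes map 0 → complete, 1–3 → mild, >3 → severe. Whether a
given dataset calls for the rank-based or the ANOVA path is left as an
explicit user choice — the package exposes both rather than an automatic
normality gate.

## Problem sizes and reproducibility

Every random draw flows through an explicit integer seed
(`withr::with_seed`), so scenes, event lists and noisy isotherms are
bit-reproducible and the fitter itself is seed-free. The shipped tests and
the acceptance script run at desk scale by design: 128–256-px scenes, 10
cells × 20 foci per rescue condition, 50 measured pairs per pool-model
condition, 100 noisy refits of the reference titration, 2000 null
simulations for family-wise error control. These sizes were chosen as the
smallest at which the measured quantities are stable to well within the
tolerances being asserted; all of them scale up linearly if heavier
validation is wanted.

## Known limitations

* The displacement-correction form and first-injection policy are
  conventions; fitted standard errors are asymptotic and differ from
  profile-likelihood or Monte-Carlo intervals, especially at extreme
  c-values.
* Detection assumes resolvable, roughly Gaussian foci; heavily clustered
  centromeres merge into single components and are then filtered by the
  area cap rather than split.
* FWHM on noisy profiles uses the raw samples (no smoothing); at very low
  marker signal-to-noise the outermost-crossing rule can latch onto a noise
  excursion. The flagged-profile mechanism and the per-condition medians
  mitigate but do not eliminate this.
* The pipeline orchestrates synthetic or CSV inputs; it does not read
  proprietary microscope or calorimeter formats.
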