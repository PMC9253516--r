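# cpcquant

Quantitative analyses for studying the interaction between the chromosomal
passenger complex (CPC — Aurora B, INCENP, Survivin, Borealin) and Shugoshin 1
(Sgo1), and the downstream cell-biological readouts of that interaction.
The package is aimed at groups doing quantitative mitosis biology who need
the same five analyses, each runnable end to end on synthetic, ground-truthed
data:

1. **ITC binding isotherms** — simulation and least-squares fitting of
   single-site (1:1) isothermal titration calorimetry data, with
   thermodynamic decomposition.
2. **Centromere ring quantification** — spot detection on anti-centromere
   (ACA) reference staining, mean marker fluorescence in a 3-pixel-wide ring
   immediately outside the centromere, cytoplasmic background subtraction,
   and normalization to a reference (rescue) condition; plus marker/GFP
   recruitment ratios for LacO–LacI tethering assays.
3. **Kinetochore-pair line profiles** — mutual-nearest-neighbour pairing of
   kinetochores (1.5 µm cap), 2-µm line profiles through each pair, and full
   width at half maximum (FWHM) of the marker signal, which discriminates a
   single inner-centromere pool from dual kinetochore-proximal pools.
4. **Mass photometry** — complex mass accounting from stated stoichiometries
   and kernel-density peak calling on per-particle mass event lists.
5. **Group statistics** — Kruskal–Wallis with Dunn's post hoc test, one-way
   ANOVA with Dunnett's test, per-group χ² rate tests, and
   chromosome-alignment phenotype scoring (0 misaligned = complete, 1–3 =
   mild, >3 = severe).

A synthetic-data module generates seeded multi-channel microscopy scenes
(Gaussian foci on noisy background, with configurable inner-centromere vs
dual-pool marker distributions), titration heat tables and mass-event
samples, so every analysis is tested against known truth.

## The models

**1:1 binding isotherm.** For injection *i* with cumulative injected volume
*V<sub>i</sub>* into a perfusion cell of volume *V*₀, total concentrations
carry the standard displacement corrections

    M_i = M0 (1 − V_i/2V0) / (1 + V_i/2V0)
    X_i = X_syr (V_i/V0)   / (1 + V_i/2V0)

the bound complex solves the single-site quadratic

    [MX] = ½ [ (N·M + X + K_D) − √((N·M + X + K_D)² − 4·N·M·X) ]

and the measured heat of injection *i* is
ΔQ<sub>i</sub> = Q<sub>i</sub> − Q<sub>i−1</sub> +
(v<sub>i</sub>/V₀)(Q<sub>i</sub> + Q<sub>i−1</sub>)/2 with
Q = [MX]·ΔH·V₀, normalized per mole injected, plus a constant
heat-of-dilution offset. The fit estimates (N, K_D, ΔH, offset) by
Levenberg–Marquardt with a deterministic multi-start over a log-spaced K_D
grid, and the free energy decomposes as ΔG = RT ln K_D = ΔH − TΔS.

**FWHM.** Profiles are sampled by bilinear interpolation along the pair
axis; the half-maximum level is (max + baseline)/2 with the baseline at the
window minimum, crossings are located by linear interpolation, and the
width spans the *outermost* left/right crossings so that dual marker pools
report their full breadth (a single Gaussian pool gives
FWHM = 2√(2 ln 2)·σ ≈ 2.3548 σ).

## Worked example

Simulate the high-affinity CPC–Sgo1 titration (50 µM titrant into 200 µl of
5 µM analyte, one 0.5-µl then fifteen 2.5-µl injections at 20 °C) with
realistic heat noise, and refit it:

```r
library(cpcquant)

sch <- titration_scheme(cell_volume_ul = 200, syringe_conc_uM = 50,
                        cell_conc_uM = 5)
iso <- simulate_isotherm(sch,
                         binding_parameters(N = 1, KD_M = 52.83e-9,
                                            dH_kcal_mol = -6.58),
                         noise_sd_kcal_mol = 0.05, seed = 42)
fit <- fit_isotherm(iso, sch)
fit
#> 1:1 binding isotherm fit
#>   N = 0.9961, KD = 52.01 nM, dH = -6.573 kcal/mol, offset = 0.00691
#>   dG = -9.770, -TdS = -3.197 kcal/mol; rss = 0.0307; c = 95.8
autoplot(fit)   # isotherm with the fitted curve
```

At 0.05 kcal/mol heat noise the fitter recovers the simulated K_D = 52.83 nM
to within 2 % (52.01 nM) and reproduces the enthalpy/entropy split
(ΔH ≈ −6.57, −TΔS ≈ −3.20 kcal/mol): the interaction is both enthalpically
and entropically favourable. `tidy(fit)` and `glance(fit)` give the
parameter table and the one-row summary.

Discriminating marker pools on synthetic chromosome spreads:

```r
inner <- spread_condition(12, "inner_only", seed = 1)
dual  <- spread_condition(12, "dual_pool",  seed = 2)
mean(inner$fwhm_um)  #> 0.356  (single pool: 2.3548 * 0.15 um = 0.353)
mean(dual$fwhm_um)   #> 1.157  (two pools at +/-0.4 um)
tab <- tibble::tibble(value = c(inner$fwhm_um, dual$fwhm_um),
                      group = rep(c("inner", "dual"), c(12, 12)))
glance(kruskal_dunn(tab))
#>   statistic    df   p.value
#> 1      17.3     1 0.0000323
```

The broader profile of the dual-pool condition is detected by the
Kruskal–Wallis test even at 12 pairs per condition.

Whole analyses can also be driven from a YAML config through
`run_pipeline()` / `write_report()`, or from a shell via the thin wrapper in
`inst/cli/cpcquant.R`.

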