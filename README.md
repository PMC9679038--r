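# gshbuffer

Red blood cells carry more than oxygen: their millimolar pool of reduced
glutathione (GSH) is a first line of defense against oxidants released by
hypoxic tissues. `gshbuffer` models hemoglobin (Hb) as an oxygen-dependent
GSH buffer — the oxygenated (R-state) tetramer holds four non-covalently
bound GSH molecules, the deoxygenated (T-state) tetramer only two, so
deoxygenation below a saturation threshold liberates free GSH into the
cytosol exactly when antioxidant capacity is needed. The package is aimed
at red-cell physiologists and biophysicists who want to fit, simulate, or
sanity-check this linkage quantitatively.

## What it computes

**Oxygen-linked release (two-state allosteric model).** Every tetramer is
in either the R or T quaternary state. With `a = pO2/KR`,

    Y(pO2)  = [a(1+a)^3 + L c a (1+ca)^3] / [(1+a)^4 + L(1+ca)^4]
    fR(pO2) = (1+a)^4 / [(1+a)^4 + L(1+ca)^4]

give the saturation and the R-state fraction. GSH release at saturation
`S` follows `phi * (n_R - n_T) * [Hb] * fT(pO2(S))` with pocket occupancy
`phi` (stoichiometric model), or a state-resolved equilibrium mass balance
using the per-state dissociation constants (`equilibrium_free_gsh()`).
GSH left-shifts and 2,3-bisphosphoglycerate (BPG) right-shifts the oxygen
equilibrium curve through the apparent allosteric constant
(`p50_with_gsh()`).

**Supporting computations.** One-set-of-sites isothermal titration
calorimetry: forward simulation of injection heats (Wiseman isotherm with
perfusion-cell displacement correction), Levenberg–Marquardt refitting,
and the decomposition `dG = -RT ln Ka = dH - T dS`. GSH/GSSG half-cell
potentials (`E_hc = -240 - 29.55 log10([GSH]^2/[GSSG])` mV). Standard-
additions quantification (`m0 = intercept/slope` with delta-method SE).
Red-cell unit conversions (g/L ↔ mM tetramer, µmol/g Hb ↔ mmol/L cell
water). Seeded synthetic-data generators for cohort, tonometry,
calorimetry and standard-additions experiments, plus analysis pipelines
(`run_cohort_analysis()`, `run_tonometry_analysis()`, `run_itc_analysis()`).

## Worked example

```r
library(gshbuffer)

# How much GSH can the Hb pool buffer?
comp <- rbc_composition()                     # MCHC 335 g/L, water fraction 0.68
hb   <- hb_mass_to_molar(335, comp)           # 5.23 mM tetramer
max_release_capacity(hb, 2)                   # 10.5 mM (2 releasable sites/tetramer)
per_gHb_to_cellwater(2.5, comp)               # oxygenated baseline: 1.23 mM
per_gHb_to_cellwater(6.0, comp)               # deeply deoxygenated: 2.96 mM
release_fraction(2.96 - 1.23, 10.5)           # ~16.5 % of the storage capacity

# Analyse a (synthetic) tonometry sweep
ton <- generate_tonometry(tonometry_scenario(), seed = 42)
run_tonometry_analysis(ton)
#> GSH release threshold: SO2* = 0.95 (baseline 2.87, amplitude 395, rate 0.0101)
#>   SSE 2.471 vs flat 41.24; F = 146, p = 3.23e-17, n = 32
#> Pocket occupancy phi = 0.177, oxygenated baseline 1.18 mM (2.4 umol/g Hb)

# Fit a one-site binding isotherm
pr <- itc_protocol()                          # 19 x 2 uL of 4 mM GSH into 85 uM Hb
fit_one_site(simulate_trace(pr, itc_thermo(4, 1/2e-6, -20)), pr)
#> One-site binding: N = 4, Ka = 5e+05 1/M (Kd = 2 uM)
#>   dH = -20, dG = -32.53, TdS = 12.53 kJ/mol at 298.15 K
```

The tonometry read-out: the fitted occupancy (`phi = 0.177`, true 0.17)
says ~18 % of the releasable pockets were loaded; the release departs from
flat as soon as the quaternary T-state fraction grows, which under the
two-state defaults is a gradual rise (the detected departure point sits
high on the saturation axis — see the vignette for why a concerted
two-state model produces a soft rather than sharp threshold). The ITC
read-out recovers the generating stoichiometry, affinity and enthalpy
exactly on noise-free data.

## Package layout

- `R/composition.R` — cell composition constants and unit conversions
- `R/redox.R` — GSH/GSSG half-cell potential
- `R/linkage.R` — two-state O2 binding, release models, threshold and
  occupancy estimators
- `R/itc.R` — titration simulation, one-site fitting, thermodynamics
- `R/quantification.R` — standard additions, per-Hb normalisation
- `R/synthetic.R` — seeded generators (cohort, tonometry, ITC, additions)
- `R/pipeline.R` — end-to-end analyses and the CSV dialect
- `vignettes/oxygen-linked-gsh-buffering.Rmd` — the methods vignette
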