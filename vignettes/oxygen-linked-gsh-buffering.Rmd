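---
title: "Oxygen-linked glutathione buffering by hemoglobin: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oxygen-linked glutathione buffering by hemoglobin: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gshbuffer)
```

## The problem

Red blood cells hold millimolar reduced glutathione (GSH), their main
non-protein thiol and a major sink for oxidants released by hypoxic
tissues. Free cytosolic GSH rises acutely when hemoglobin (Hb)
deoxygenates — without new synthesis and without recovery from the
oxidized (GSSG) pool. The mechanism modelled here is non-covalent
buffering by Hb itself: the oxygenated (R-state) tetramer carries four
GSH molecules in central-cavity pockets, the deoxygenated (T-state)
tetramer only two, so the R-to-T quaternary transition liberates up to
two GSH per tetramer. `gshbuffer` turns this picture into a quantitative,
testable model and packages the supporting computations: calorimetric
binding analysis, redox potentials, standard-additions quantification,
unit conversions, and synthetic-data generators for every input.

## The linkage model

### Oxygen binding

Oxygen binding uses a concerted two-state framework: every tetramer is
entirely R or entirely T, with four equivalent oxygen sites per state.
With $\alpha = p\mathrm{O}_2 / K_R$, allosteric constant $L$ (T/R ratio
at zero oxygen) and affinity ratio $c = K_R/K_T$:

$$Y = \frac{\alpha(1+\alpha)^3 + Lc\alpha(1+c\alpha)^3}
          {(1+\alpha)^4 + L(1+c\alpha)^4},
\qquad
f_R = \frac{(1+\alpha)^4}{(1+\alpha)^4 + L(1+c\alpha)^4}.$$

The quaternary state, not fractional saturation per se, controls the GSH
pockets — which is why a two-state model is the natural scaffold for
all-or-none per-tetramer release. The measured quantities in this field
(saturation, P50) do not identify $L$, $c$, $K_R$ separately, so the
defaults are conventional textbook-order values for human Hb, chosen
once and configurable: $L = 1.7\times10^5$, $c = 0.014$, and $K_R$
calibrated by root-finding so half-saturation falls at
$P_{50} = 26$ mmHg. An empirical Hill mode
($Y = p^n/(p^n + P_{50}^n)$, default $n = 2.7$) is available where only a
saturation curve is needed; quaternary-state bookkeeping requires the
two-state mode.

At $c = 1$ the two states have equal affinity and the curve collapses to
$\alpha/(1+\alpha)$ for any $L$ — a closed-form identity the tests assert
to $10^{-12}$.

### A soft, not sharp, transition

A consequence worth stating plainly: with four oxygen sites the R-to-T
switch spreads over a sizeable range of the saturation axis. Under the
defaults, $f_T \approx 0.06$ at 98% saturation, $0.15$ at 90%, $0.52$ at
60% and $0.92$ at 20%. Released GSH therefore rises gradually from high
saturation rather than being exactly flat above a corner. The model does
concentrate release at low saturation — release at 90% saturation is
about 16% of that at 20%, and the tests assert it stays below 20% — but
a concerted two-state mechanism cannot produce a literal corner at 50%
saturation. Observed release curves that are genuinely flat above ~50–60%
are therefore *sharper* than this two-state account; the package keeps
both tools and lets the data speak: the mechanistic release model for
occupancy estimation, and an empirical threshold estimator (below) for
locating the departure point.

### Release models

Two deliberately different release models ship:

- **Stoichiometric** (`stoichiometric_release()`,
  `predicted_free_gsh()`): each tetramer entering T sheds its
  $n_R - n_T$ releasable pockets, so
  $\mathrm{released} = \phi\,(n_R-n_T)\,[\mathrm{Hb}]\,f_T$, with mean
  pocket occupancy $\phi \in [0,1]$. This reproduces the desk arithmetic
  of the buffering capacity and is the default for all reproduction
  work.
- **Equilibrium mass balance** (`equilibrium_free_gsh()`): free GSH $g$
  solves
  $g + [\mathrm{Hb}](f_R n_R \tfrac{g}{g+K_{d,R}} + f_T n_T
  \tfrac{g}{g+K_{d,T}}) = g_{total}$
  by bisection (the left side is strictly increasing, so the root is
  unique; residual $< 10^{-9} g_{total}$).

These disagree at cellular concentrations, and the disagreement is
informative: the calorimetric affinities are micromolar
($K_d$ = 2 µM oxy, 17 µM deoxy), so at millimolar total GSH a simple
equilibrium predicts essentially saturated pockets in *both* states and
only a small free-GSH excursion on deoxygenation, while measured free
GSH moves by more than a millimole per litre. Equally, micromolar
affinities imply that millimolar free GSH should drive the apparent
allosteric constant so far down that `p50_with_gsh(5)` returns ~1.2 mmHg
— a collapse, not the modest affinity increase actually observed. The
package makes no attempt to hide this tension: both models are exposed,
the stoichiometric one (whose $\phi$ absorbs whatever keeps occupancy
partial in vivo — compartmentalisation, competing ligands, activity
effects) is the default, and the equilibrium one is kept as the
thermodynamically self-consistent reference.

### Occupancy and threshold estimation

`fit_phi()` exploits that the stoichiometric model is linear in
$(\mathrm{baseline}, \phi)$: ordinary least squares on the design
$[1, (n_R-n_T)[\mathrm{Hb}]f_T(S_i)]$, with $\phi$ clipped to $[0,1]$.
Saturations must span a range over which $f_T$ varies, otherwise the fit
aborts with an identifiability error.

`estimate_threshold()` fits the empirical flat-then-exponential curve

$$g(S) = a \;\; (S \ge S^*), \qquad
  g(S) = a + b\,(e^{k(S^*-S)}-1) \;\; (S < S^*)$$

by exhaustive grid search over $S^* \in \{0.05, \dots, 0.95\}$ (step
0.01), a nested 1-D optimisation over the rate $k \in [0.01, 30]$, and
linear least squares over $(a, b)$. Whether any threshold exists is
decided by an F-style SSE-ratio test against the constant model (3 extra
parameters; default $\alpha = 0.05$); flat data return a "no threshold"
result rather than a number. The grid bounds double as the resolution
(±0.01) and the rate interval covers everything from near-linear rises
to near-step curves on the unit saturation interval.

Simulation studies in the test suite characterise the estimator: with
noise of 0.2 µmol/g Hb the threshold location carries an inherent
uncertainty of roughly ±0.1 on a single 32-point sweep (verified against
a brute-force rate grid — this is the likelihood surface, not the
optimiser). The recovery study therefore uses seven replicate sweeps
(224 points), the replication level of the tonometry experiment the
generator emulates, and recovers a true threshold of 0.50 within ±0.05
in ≥90% of 20 seeded runs.

## Calorimetry

`simulate_trace()` implements the one-set-of-sites (Wiseman) isotherm
with the standard perfusion-cell displacement convention: after
cumulative injected volume $\Delta V$ into active volume $V_0$, cell
concentrations are
$M = M_0\frac{1-\Delta V/2V_0}{1+\Delta V/2V_0}$,
$X = X_0\frac{\Delta V/V_0}{1+\Delta V/2V_0}$;
the cumulative heat is
$Q = \frac{N M \Delta H V_0}{2}\left[B - \sqrt{B^2 - 4X/(NM)}\right]$
with $B = 1 + \frac{X}{NM} + \frac{1}{N K_a M}$, and the observed
injection heat adds the displaced-volume correction
$\delta Q_i = Q_i - Q_{i-1} + \frac{v_i}{V_0}\frac{Q_i+Q_{i-1}}{2}$.
The default protocol (19 × 2 µL of 4 mM ligand into 200 µL of 85 µM
macromolecule at 298.15 K) carries the molar ratio past 8, covering the
isotherm for stoichiometries up to 4. Heats are joules internally;
`ucal_to_uJ()` converts instrument output recorded in µcal.

`fit_one_site()` is Levenberg–Marquardt least squares over
$(\log N, \log_{10} K_a, \Delta H)$, optionally plus a constant
per-injection heat-of-dilution offset (default on for real data, whose
dilution subtraction is rarely perfect). Starting values: $N_0$ from the
molar ratio at half the total cumulative heat, $\Delta H_0$ from the
first injection, $K_{a,0} = 10^5$ M$^{-1}$, with a restart grid
$\log_{10}K_a \in \{3,\dots,8\}$ if the first attempt stalls. Traces with
zero heats abort (enthalpy unidentifiable); near-constant traces warn
that the stoichiometry is poorly identifiable. The forward model is
validated against an independent per-injection equilibrium solver
(bisection on the free-ligand mass balance) to $10^{-9}$, and noiseless
simulate-then-fit round trips recover all parameters to <0.1% across
$N \in \{1,2,4\}$, $K_d \in \{1,5,20,100\}$ µM.

A caution on precision, quantified in the test suite: with heat noise of
2% of the largest injection heat, the Cramér–Rao bound puts the relative
standard deviation of $\hat K_d$ at ~13% for the steep oxy-type isotherm
($N=4$, $K_d=2$ µM; c-value $NM_0/K_d \approx 170$) and ~12% for the
deoxy-type one ($N=2$, $K_d=17$ µM), and the fitted estimator is
empirically efficient. Affinity estimates from single steep traces at
this noise level therefore carry ±15%-or-worse uncertainty as a matter
of information content, not of fitting quality. Recovery studies on
synthetic traces fit without the dilution offset, since the generator
(like a dilution-subtracted experiment) adds none.

`thermo_decompose()` applies $\Delta G = -RT\ln K_a$,
$T\Delta S = \Delta H - \Delta G$, $K_d = 1/K_a$; every returned
parameter set satisfies these identities by construction.

## Redox potential

`half_cell_potential()` evaluates the fixed 25 °C, pH 7.0 form
$E_{hc} = -240 - \frac{59.1}{2}\log_{10}\frac{[GSH]^2}{[GSSG]}$ mV, with
both concentrations in mol/L. The squared numerator makes the log
argument dimensionful; the mol/L convention is part of the definition,
and no temperature or pH generalisation is attempted. Doubling GSSG
raises the potential by exactly $29.55\log_{10}2 \approx 8.90$ mV;
doubling GSH lowers it by twice that.

## Quantification and unit conversions

Standard additions: unweighted least squares of intensity on added
amount, $m_0 = \hat\beta_0/\hat\beta_1$, SE by the delta method including
the intercept–slope covariance (a residual bootstrap is available behind
a flag). The estimate is invariant to intensity rescaling and
equivariant under shifts of the addition axis; a non-positive slope is a
hard error since the signal must increase with additions. No
evaporation or volume corrections are applied to the additions.

Unit conversions are pure functions of an `rbc_composition()` object.
Defaults: MCHC 335 g/L; Hb tetramer molar mass 64 000 g/mol (335 g/L ↔
5.23 mM to two decimals); water volume fraction 0.68. The often-quoted
water:dry ratio 0.67:0.33 would give 1.25/3.00 mM for the worked
2.5/6.0 µmol/g Hb conversions, while 0.68 reproduces the reference
values 1.23/2.96 mM exactly — the default is calibrated to those worked
examples, with 0.67 one argument away. Note that the familiar
"1.73 mM released" is the subtraction of the two *rounded* values; the
unrounded chain gives 1.724 mM and 16.5% of the 10.5 mM capacity either
way.

## Synthetic data: what it emulates, and what it does not

All generators are pure functions of (parameters, seed); each draws from
its own derived stream, so adding one generator never perturbs another's
output. Concentration draws are redrawn, not clipped, at zero.

- **Cohort** (`generate_cohort()`): subjects × sampling days, a
  per-subject random intercept on GSH, condition means 3.4 ± 0.65
  (sea level) and 4.6 ± 0.64 µmol/g Hb (high altitude), GSSG independent
  of condition. The GSSG (0.8 ± 0.15 µmol/g Hb), venous saturation
  (70/45%), hemoglobin (145/160 g/L) and between-subject (0.3 µmol/g Hb)
  defaults are invented, plausible values — the quantities they stand in
  for are reported only graphically — and are flagged as such in the
  documentation.
- **Tonometry** (`generate_tonometry()`): control and
  synthesis-inhibited (BSO) modes draw around the oxygen-linked
  prediction and are identical in distribution (and, per seed,
  identical), encoding that the rise does not depend on de novo
  synthesis; thiol-blocked (NEM) mode is flat near zero. Noise
  0.2 µmol/g Hb.
- **Calorimetry** and **standard additions**: the exact forward models
  plus i.i.d. Gaussian noise.

What passing tests on these generators shows is *internal* consistency:
every analysis stage, run on its generator's noiseless output, returns
the generating parameters (the closed-loop property), and does so
stably under realistic noise. What they cannot show is fidelity to real
blood: real tonometry sweeps have serially correlated errors and
hysteresis, real cohorts have day effects and dropout, real ITC traces
have first-injection artifacts and baseline drift. The generators make
no attempt at any of these.

The statistical pipeline simplification is worth restating: the cohort
analysis replaces a repeated-measures ANOVA (subject as random factor,
four planned contrasts) with four within-subject paired t-tests on
per-subject day means — high altitude vs pre-sojourn baseline, early vs
late altitude, pre vs post, and early vs late post-descent. P-values
are unadjusted by default (Holm behind a flag). The level of the first
contrast was checked by a 200-seed null simulation (equal condition
means, subject effects retained): empirical type-I error 0.06 at
nominal 0.05. A null *simulation* was chosen over permuting condition
labels in one dataset because label permutation on data with a real
effect does not target the test's level.

## Numerical choices

- Monotone 1-D inversions (saturation → pressure, KR calibration,
  equilibrium mass balance) use bisection or `uniroot` with brackets
  stated in the function documentation; saturation inversion is accepted
  at $|Y - S| < 10^{-9}$.
- Saturation is a fraction internally; percent columns (suffix
  `_percent`) are converted at the pipeline boundary.
- Edge cases: saturation 1 maps to the high-pressure limit $f_T = 0$;
  saturation 0 to $f_T(p\mathrm{O}_2{=}0) = L/(1+L)$; zero total GSH or
  zero Hb short-circuit the equilibrium solver.
- BPG is a pure T-state effector (one site, literature $K_d$ 4.75 mM
  oxy / 0.1 mM deoxy) multiplying the apparent allosteric constant; no
  GSH–BPG site competition is modelled, consistent with the
  non-overlapping binding sites.
- The threshold grid step (0.01) bounds the location resolution; ties in
  the grid search resolve to the first (lowest) minimiser.

## Problem sizes

The shipped studies are sized to characterise the estimators while
staying desk-scale: 20 seeds for the ITC and tonometry recovery studies,
200 seeds for the standard-additions coverage and cohort level studies,
500 subjects for the law-of-large-numbers check, 7 × 32 points for the
threshold recovery. These sizes are the package's own choices and are
stated here so they can be scaled up for sharper characterisation.

## Known limitations

- No kinetics: all binding is equilibrium; association/dissociation
  rates, and hence the timescale of release, are out of scope.
- No Bohr-effect, CO₂ or pH coupling in the oxygen model; the redox
  potential is the fixed 25 °C / pH 7.0 form.
- The µM-calorimetry vs mM-cytosol tension described above is exposed,
  not resolved.
- Whether acid deproteinization releases the non-covalently bound pool
  (changing what "free GSH" means operationally) is not modelled; the
  measured quantity is taken at face value.
- The paired-contrast scheme is a simplification of a mixed-effects
  analysis and will be conservative or anticonservative in designs with
  strong day-level correlation structure.
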