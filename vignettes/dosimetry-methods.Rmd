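---
title: "Internal dosimetry of an F-18 PET tracer: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Internal dosimetry of an F-18 PET tracer: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdose)
```

# The problem

A first-in-humans dosimetry study of an F-18 labelled tracer measures
decay-corrected organ activity (as fractions of the injected activity) in
volumes of interest over eight whole-body PET acquisitions spread across
three scan sessions, collects urine between sessions, and converts these
measurements into organ absorbed doses (mGy/MBq) and an ICRP-60 effective
dose (mSv/MBq) via the MIRD schema. `mirdose` implements that analysis
chain end to end, and ships a seeded synthetic-cohort generator calibrated
to the published whole-body biodistribution of ¹⁸F-rhPSMA-7.3 so that
every stage can be exercised and validated without subject-level data,
which were never deposited publicly.

# Residence times from time–activity curves

PET scanners report decay-corrected activity. All integrals therefore
re-apply the physical decay of F-18 explicitly (half-life 109.77 min,
$\lambda_p = 0.3789\,\mathrm{h}^{-1}$); the fitted exponential is a purely
*biologic* washout. For a source organ with decay-corrected curve $v(t)$
the residence time (cumulated activity per unit injected activity) is

$$\tau = \int_0^\infty v(t)\, e^{-\lambda_p t}\, dt
  \;=\; \underbrace{\int_0^{t_8} \hat v(t) e^{-\lambda_p t} dt}_{\text{observed span}}
  \;+\; \underbrace{\frac{A(t_8)\, e^{-\lambda_p t_8}}{\lambda_p + k_{bio}}}_{\text{analytic tail}},$$

with a linear rise from $(0,0)$ to the first sample. The washout fit
(`fit_washout()`) uses only the descending part of the curve: the global
maximum sample (latest sample on ties, which maximises the number of
descending points) starts the fit window, and $A_0 e^{-k_{bio} t}$ is
fitted by bounded nonlinear least squares. A curve still rising at the
last acquisition gets the conservative $k_{bio} = 0$: its tail decays by
physical decay only.

Numerical choices worth stating:

* **Within-segment decay weighting.** The observed-span integral
  interpolates the *decay-corrected* curve linearly between samples and
  carries $e^{-\lambda_p t}$ analytically inside each segment. A plain
  trapezoid on the decayed samples (`method = "trapezoid"`) overshoots by
  1–3% across the 76-min gap between sessions 1 and 2, because
  $e^{-\lambda_p t}$ is strongly convex over such a gap; the default
  method is exact for a pure physical-decay curve and keeps every
  washout-type organ within 1% of a fine-grid quadrature oracle at the
  default 8-point schedule.
* **Slow-uptake organs.** Organs whose uptake is still completing at the
  last acquisition (salivary-type kinetics with $k_{up} \le 1/\mathrm{h}$ in
  the generator) cannot be integrated to 1% from eight samples: the
  conservative flat tail undershoots by up to ~2.5%. These are
  near-zero-fraction organs, so the dosimetric effect is negligible.
* **Peak-selection bias.** For curves whose early decline is smaller than
  the measurement noise (liver, $k_{bio} = 0.08/\mathrm{h}$, declines 0.8%
  between the 1- and 7-min scans while the noise is 5%), the global-max
  rule preferentially starts the fit at an upward-fluctuated sample and
  inflates $k_{bio}$ by ~7% in the median. The absolute effect on $\tau$
  is second order ($k_{bio} \ll \lambda_p$ in the tail denominator), and
  decisively descending organs recover their rate within 5%.

The remainder of body closes the activity balance: a source retaining the
entire injection forever would have $\tau = 1/\lambda_p = 2.639$ h, and
each void of decay-corrected fraction $u$ at time $t_v$ forfeits
$u\,e^{-\lambda_p t_v}/\lambda_p$. Summing the bladder-content residence
time and the per-void forfeits over the periodic voiding schedule gives
exactly $f_u(1/\lambda_p - 1/(\lambda_p+\lambda_b))$ independent of the
voiding interval — which is why, in the pipeline, only the bladder-wall
dose responds to the modeled interval.

# The dynamic bladder model

Urine collections (attributed to their end times, since a collection
empties the bladder at the void) yield the cumulative decay-corrected
excreted fraction, fitted as $F(t) = f_u(1 - e^{-\lambda_b t})$ with
$0 \le f_u \le 1$, $\lambda_b \ge 0$. Under periodic complete voiding
every $T$ hours from injection (the convention of the classic dosimetry
software: modeled intervals, not the subjects' actual voids), the
bladder-content residence time has the closed form

$$\tau_{bl} = f_u\,
 \frac{\dfrac{1-e^{-\lambda_p T}}{\lambda_p} -
       \dfrac{1-e^{-(\lambda_p+\lambda_b) T}}{\lambda_p+\lambda_b}}
      {1-e^{-(\lambda_p+\lambda_b) T}}.$$

For $\lambda_b T < 10^{-8}$ the numerator cancels catastrophically in
floating point and a first-order series in $\lambda_b$ is used; the limit
vanishes only when $f_u \lambda_b$ does. The closed form is verified
against numerical integration of the piecewise ODE (accrual, physical
decay, instantaneous voiding) to $10^{-6}$ relative over a
$f_u \times \lambda_b \times T$ grid.

With kinetics fitted to the published cumulative urine fractions
(7.2/11.4/14.8% at 111/194/263 min: $f_u = 0.382$,
$\lambda_b = 0.111/\mathrm{h}$, biologic half-life ≈ 6.2 h), the 3.5-h
interval gives 2.99× the 1-h residence time — consistent with the
published doubling of the bladder-wall dose once the interval-independent
cross-dose from neighbouring sources is added.

The image-based estimator (`bladder_residence_voi()`) reproduces the
study's bookkeeping: each scan's VOI concentration is multiplied by the
voided-urine volume measured at the end of that scan's session, the
activity series resets at each void, and the last value is carried with
physical decay. Applying the end-of-session volume to mid-session scans
overestimates early-session activity (the bladder is still filling), while
using the voided volume (the residual is not observable without imaging)
underestimates the content volume; net, the estimator runs ~20% above the
matched dynamic-model value on noise-free synthetic subjects. The two are
different estimators of the same quantity and agree within 30%; the
dynamic-model values feed the dosimetry, as in the study.

# Dose engine

The MIRD contraction $D(T) = \sum_S \tau_S\, S(T\!\leftarrow\!S)$ runs on
a reference 70-kg hermaphroditic adult phantom extended with four glands
with assigned masses (parotid 25 g, submandibular 12.5 g, sublingual
12.5 g, lacrimal 5 g). Real radionuclide S-value tables are external
reference data; the package generates a clearly-labelled *synthetic*
table from transparent energy bookkeeping (F-18 nonpenetrating energy
$\Delta_{np} = 139.4$ mGy·g/(MBq·h) deposited locally, half of it in the
wall for content regions, an annihilation-photon whole-body bath for
cross-dose), sufficient for exercising and property-testing the engine;
a real table can be substituted at the CSV boundary. The synthetic
table deliberately assigns the bladder content no photon bath so that the
voiding interval affects exactly one report row, which mirrors the
published result at printed precision and gives the pipeline a sharp
invariant to test.

The four glands have no geometry in classic phantom tables; they
self-irradiate via the unit-density sphere model
($D = \tau\,\Delta_{np}/m$, absorbed fraction 1 for nonpenetrating
emissions, photon cross-dose ignored) and contribute their residence time
to the remainder source for other targets.

## Effective dose and the remainder convention

ICRP-60 weights are used (the study's dosimetry software predates
ICRP-103); the weight set is configurable. Surrogates: gonads = mean of
testes and ovaries (hermaphroditic phantom, sex-averaged as in the
reference-phantom tradition); colon = mass-weighted mean of the upper and
lower large-intestine walls; esophagus = thymus.

How the 0.05 remainder weight is applied is the one genuinely open design
point, because the classic software's implementation is not documented.
Three conventions are implemented:

* `"mass_weighted"` — the ICRP-60 base rule (mass-weighted mean over
  adrenals, brain, small intestine, kidneys, muscle, pancreas, spleen,
  thymus, uterus). Muscle dominates the mass and dilutes the hot small
  organs: applied to the published organ-dose table it yields
  0.0113 mSv/MBq, 20% below the published effective dose.
* `"icrp60_split"` — the ICRP-60 footnote rule: when one remainder tissue
  exceeds every explicitly weighted organ (here the adrenals at
  0.184 mGy/MBq vs liver 0.062), 0.025 goes to that tissue and 0.025 to
  the mass-weighted mean of the rest. This yields 0.0157 mSv/MBq, 11%
  above the published value.
* `"olinda"` (default) — an unweighted arithmetic mean over the remainder
  tissues. This reproduces the published effective doses to within 2.5%
  (0.0137 vs 0.0141 mSv/MBq at 3.5 h; 0.0134 vs 0.0138 at 1 h) and is
  therefore the best available reconstruction of how the study's software
  actually behaved; it is the package default for exactly that reason.

The splitting rule remains fully implemented and is property-tested both
ways (firing and not firing) against a brute-force case-analysis oracle.

# The synthetic cohort

Each organ follows
$A(t) = f_{peak}\,(1-e^{-k_{up} t})\,e^{-k_{bio} t}$ (decay-corrected
fraction of injected activity) — the simplest form supporting the
continuing-uptake/washout distinction the analysis must handle; the study
published sampled values, not an organ model. Calibration:

* For the six organs with published 1-min cohort means (liver 15.8%,
  heart content 7.4%, cortical bone 3.5%, muscle 24.3%, brain 0.8%,
  pancreas 0.6%), $f_{peak}$ is solved so the noise-free model hits those
  values exactly at 1 min. First-pass organs get
  $k_{up} = 1000/\mathrm{h}$ — effectively instantaneous on the
  acquisition grid, as a bolus is.
* Organs described as near-zero get $f_{peak} \le 0.001$; delayed-uptake
  organs (kidneys, spleen, red marrow, salivary and lacrimal glands) get
  $k_{up}$ between 0.5 and 2 per hour, placing their peaks between 1 and
  6 h.
* Urinary kinetics are the least-squares fit to the published cumulative
  fractions (above). Inter-subject variability is lognormal with mean
  exactly 1, so cohort means stay calibrated; CVs come from the published
  ranges via range ≈ ±2 SD for n = 6 (liver 4.9%, muscle 10.4%, urine
  16%), 15% where no range is printed. Measurement noise is multiplicative
  lognormal, 5%.
* Urine volumes come from a production rate (lognormal around
  1.4 mL/min) plus a ~40 mL post-void residual; the recorded
  bladder-volume measurements are voided volumes, which is what a study
  can measure without imaging.
* Sexes alternate so n = 6 gives 3 men and 3 women; breasts, uterus and
  ovaries exist only for women, testes only for men. Injected activity is
  uniform in 225 MBq ± 10%.
* A remainder-of-body curve closes the balance so that organs + bladder +
  voided urine + remainder = 1 at every sampled time, exactly at zero
  noise.

What the generator does *not* emulate: image-level effects (partial
volume, VOI misalignment, reconstruction noise correlations), plasma
metabolites, multi-compartment organ kinetics, or true anatomical
variation in organ mass. Passing tests therefore demonstrate that the
*analysis chain* is correct and well-calibrated under its stated
assumptions, not that those assumptions capture everything in real PET
data.

# Problem sizes and reproducibility

The test suite and the acceptance script use 6-subject cohorts (200
seeded replicates for calibration checks, ~1 200 subjects total), 500
single-subject replicates for excretion-parameter recovery, and 1 000
noise replicates for washout-rate recovery — sizes at which the Monte
Carlo standard errors are a few per mil, chosen so the whole suite runs
in minutes on a laptop. Every random draw is governed by a single integer
seed; the same seed reproduces every CSV byte for byte.

# Known limitations

* Absolute organ doses from the bundled pipeline are only as good as the
  *synthetic* S-value table; real Cristy–Eckerman/OLINDA tables must be
  supplied for publication-grade organ doses. The effective-dose
  weighting, by contrast, is exercised directly against the published
  organ-dose table.
* The mono-exponential washout is the study's own convention; organs with
  genuinely multi-phasic kinetics are out of scope.
* The 0.012 mGy/MBq published bladder-wall dose at a 3.5-h interval
  implies a wall←content S-value of ≈0.09 mGy/(MBq·h); the synthetic
  table's transparent bookkeeping is of the same order but not calibrated
  to it.
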