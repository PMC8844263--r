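# mirdose

Internal radiation dosimetry for F-18 PET radiopharmaceuticals, built the
way a first-in-humans biodistribution study analyses its data: organ
time–activity curves → mono-exponential biologic washout fits → residence
times (cumulated activity per unit injected activity) → MIRD-schema organ
absorbed doses on a reference adult phantom → ICRP-60 effective dose,
with the urinary bladder handled by the dynamic voiding model. A seeded
synthetic-cohort generator, calibrated to the published whole-body
biodistribution of ¹⁸F-rhPSMA-7.3 in six healthy volunteers, makes the
whole chain testable without any subject-level data.

The package is for dosimetry and pharmacokinetics practitioners who want
a scripted, reproducible, testable version of an analysis that is
traditionally spread across spreadsheets and GUI dosimetry software.

## The model in brief

All inputs are decay-corrected, so physical decay
(λ<sub>p</sub> = ln 2 / 109.77 min) is re-applied explicitly everywhere:

* **Residence time** of a source organ with decay-corrected curve *v(t)*:
  τ = ∫ v(t) e<sup>−λ_p t</sup> dt, integrated as a linear interpolant
  with exact decay weighting over the observed span, plus the analytic
  tail A(t₈) e<sup>−λ_p t₈</sup>/(λ_p + k_bio) from a least-squares fit
  of A₀ e<sup>−k_bio t</sup> to the descending part of the curve only.
* **Dynamic bladder model**: cumulative urinary excretion
  F(t) = f_u (1 − e<sup>−λ_b t</sup>) is fitted to the timed urine
  collections; under periodic voiding every *T* hours the bladder-content
  residence time has a closed form (verified against an ODE oracle to
  1e−6) that the pipeline evaluates at 1 h and 3.5 h.
* **MIRD schema**: D(target) = Σ_sources τ_S · S(target←source); four
  added glands (parotid 25 g, submandibular 12.5 g, sublingual 12.5 g,
  lacrimal 5 g) self-irradiate via the unit-density sphere model
  D = τ Δ<sub>np</sub>/m.
* **Effective dose**: E = Σ w_T H_T with ICRP-60 weights; the 0.05
  remainder is configurable (arithmetic mean, mass-weighted mean, or the
  ICRP-60 splitting rule — see the methods vignette for why the
  arithmetic mean is the default).

## Worked example

```r
library(mirdose)

coh <- generate_cohort(n_subjects = 6, seed = 1)
coh
#> <dosim_cohort> 6 subjects (3M/3F), seed 1
#>   organs: 29; acquisitions at 1, 7, 20, 40, 65, 88, 164, 234 min

# per-subject residence times (organ fits + dynamic bladder at 3.5 h)
taus <- subject_residence_times(coh, interval_h = 3.5)

report <- build_dose_report(taus[, c("subject_id", "organ", "tau_h")])
head(tidy(report), 5)
#> # A tibble: 5 × 3
#>   organ                mean_mgy_per_mbq sd_mgy_per_mbq
#>   <chr>                           <dbl>          <dbl>
#> 1 submandibular_glands           0.0793        0.0173
#> 2 urinary_bladder_wall           0.0531        0.0126
#> 3 adrenals                       0.0475        0.00376
#> 4 lacrimal_glands                0.0417        0.00731
#> 5 parotid_glands                 0.0349        0.00275
glance(report)
#> # A tibble: 1 × 4
#>   effective_dose_msv_per_mbq effective_dose_sd n_subjects n_organs
#> 1                     0.0159          0.000617          6       28
```

Organ doses above use the package's clearly-labelled *synthetic* S-value
table (real radionuclide S-value tables are external reference data that
can be substituted via CSV); the gland-dominated ranking reflects the
sphere-model self-dose of very small organs. Applying the ICRP-60
weighting directly to the *published* organ-dose table of the
¹⁸F-rhPSMA-7.3 study reproduces its effective dose:

```r
e <- effective_dose(reported_organ_doses()[, c("organ", "dose_mgy_per_mbq")])
round(e, 4)
#> [1] 0.0137        # published: 0.0141 mSv/MBq (3.5-h voiding interval)
round(300 * e, 2)
#> [1] 4.12          # published: a 300 MBq administration ~ 4.2 mSv
```

Urinary excretion and the voiding-interval dependence:

```r
k <- fit_excretion(coh$urine[coh$urine$subject_id == "S01", ])
k
#> <bladder_kinetics> f_u = 0.3636, lambda_b = 0.1069/h (biologic half-life 6.49 h)
bladder_residence_dynamic(k, 3.5)
#> # A tibble: 1 × 3
#>   organ                   tau_h interval_h
#> 1 urinary_bladder_content 0.114        3.5
```

The full pipeline (cohort CSVs, residence-time table, one dose report per
voiding interval, run log) is one call — or one shell command via the
thin wrapper in `inst/cli/dosim-pipeline.R`:

```r
run_pipeline(pipeline_config("out", seed = 1, n_subjects = 6))
```

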