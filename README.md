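# DosePaintR

Dose painting by numbers for glioblastoma radiotherapy, from
multiparametric MRI to evaluated treatment plans, as a tested R package.

Radiotherapy for glioblastoma prescribes a uniform 60 Gy to an expanded
target volume, yet most tumours recur locally: infiltrating, partly
radio-resistant tumour extends beyond the contrast-enhancing lesion.
*Dose painting by numbers* instead prescribes dose voxel by voxel from
imaging surrogates of tumour biology. DosePaintR implements that workflow
end to end for researchers in radiotherapy physics and quantitative
imaging:

1. **Tumour probability.** Standardized apparent-diffusion-coefficient
   (ADC) and relative cerebral-blood-flow (rCBF) maps are combined by a
   biopsy-validated linear infiltration model,
   `L_i = 1.64 + 1.80·ADC_i + 1.43·rCBF_i`, mapped through a logistic (or
   clamped-linear) link to a per-voxel probability `p_i` in the CTV, with
   GTV voxels overridden to 1 and CSF to 0.
2. **Prescription.** `D_i = D_min + (D_max − D_min)·p_i` with
   `D_min = 60` Gy and `D_max = 80` Gy; the CTV-to-PTV setup ring gets the
   base 60 Gy; the inverse prescription `D_max − D_i` is emitted for
   planning systems that need it.
3. **Planning.** A transparent surrogate optimizer (non-negative latent
   fluence field convolved with a 5 mm FWHM Gaussian point-spread
   function, projected gradient descent) produces deliverable-style dose
   distributions under clinical goals (GTV ≥ 76.8, CTV ≥ 61.2,
   PTV ≥ 60.6, PTV ≤ 77.5 Gy) and organ-at-risk limits, in dose-painting
   and standard uniform-60-Gy modes.
4. **Evaluation.** Quality factor
   `QF = 100 − (100/n)·Σ|D_plan − D_rx|/D_rx`, DVH metrics (Dmean, Dmin,
   Dmax, D98%, V60Gy, V76Gy, V80Gy), tumour control probability
   `TCP = exp(−C·Σ p_i·exp(−α·D_i))` with `α = 0.12 Gy⁻¹` and `C`
   calibrated so standard plans hit the 27% one-year progression-free
   survival benchmark, and paired Wilcoxon signed-rank comparisons.
5. **Phantoms.** A synthetic head generator (brain ellipsoid, ventricular
   CSF, spherical GTV, geometric OARs, ground-truth infiltration field
   built by inverting the infiltration model) makes the whole pipeline
   reproducible without patient data.

Structure margins follow clinical practice: CTV = GTV + 1.5 cm clipped to
the brain, PTV = CTV + 0.3 cm. Volumes are exchanged as NIfTI; reports as
CSV/JSON. See the vignette `vignettes/dose-painting-workflow.Rmd` for the
models, assumptions, numerical choices and limitations.

## Worked example

```r
library(DosePaintR)

res <- runCase(defaultRunConfig(seed = 1L), verbose = FALSE)
subset(res$comparison, structure == "GTV")
```

```
  structure metric   standard dose_painting difference       units
1       GTV     QF  98.903797     97.051926 -1.8518716           %
2       GTV  Dmean  60.657722     77.641541 16.9838189          Gy
3       GTV   Dmin  60.334957     75.700399 15.3654417          Gy
4       GTV   Dmax  60.839277     78.120111 17.2808343          Gy
5       GTV   D98%  60.521119     76.540679 16.0195600          Gy
6       GTV  V60Gy 100.000000    100.000000  0.0000000           %
7       GTV  V76Gy   0.000000     99.875931 99.8759305           %
8       GTV  V80Gy   0.000000      0.000000  0.0000000           %
9       GTV    TCP   0.948014      0.993064  0.0450503 probability
```

Reading the table: both plans are highly conformal to their own
prescriptions (QF 97–99%), but the dose-painting plan escalates the GTV —
mean dose rises from ~60.7 to ~77.6 Gy and nearly the whole GTV receives
at least 76 Gy — while the standard plan, by construction, delivers no
boost (V76Gy = 0). The TCP gain is computed at the default calibration
`C = 0.032`; `runCohort()` recalibrates `C` on the cohort's own standard
plans before comparing. `res$constraintsDp` lists the achieved
organ-at-risk doses against their limits, and
`runCase(..., outDir = "case01")` writes every stage's volumes, DVHs and
reports to disk.

A cohort analysis with per-metric Wilcoxon p-values:

```r
coh <- runCohort(defaultRunConfig(seed = 1L), nCases = 5)
coh$summary
```

A command-line wrapper with `simulate`, `contour`, `probability`,
`prescribe`, `plan`, `run` and `cohort` subcommands is installed at
`inst/scripts/dosepaint.R`:

```sh
Rscript inst/scripts/dosepaint.R run --seed 1 --out case01
```

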