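---
title: "Dose painting by numbers from multiparametric MRI: models, assumptions and numerical choices"
author: "DosePaintR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose painting by numbers from multiparametric MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Glioblastoma recurs locally in the large majority of patients despite
uniform 60 Gy radiotherapy, because tumour cells infiltrate beyond the
contrast-enhancing lesion and sub-populations of them are radio-resistant.
Dose painting by numbers replaces the uniform prescription with a voxel-wise
one driven by imaging surrogates of tumour biology: apparent diffusion
coefficient (ADC) maps reflect cellularity and relative cerebral blood flow
(rCBF) maps reflect perfusion. DosePaintR implements that workflow end to
end — probability modelling, prescription, a transparent surrogate
optimizer, and quantitative evaluation against the standard uniform plan —
with a synthetic phantom generator in place of patient imaging, so that
every stage is reproducible and testable on a desktop.

## The infiltration model and its link function

The tumour-probability model is a fixed linear combination of standardized
inputs,

$$L_i = 1.64 + 1.80\,\mathrm{ADC}_i + 1.43\,\mathrm{rCBF}_i,$$

with coefficients taken as constants from a biopsy-validated logistic
regression; refitting them is out of scope. The linear predictor is
unbounded, yet it is used as a probability. Because the source model is a
logistic regression, the package's default link maps $L_i$ through the
logistic sigmoid, $p_i = 1/(1+e^{-L_i})$; a `clamped-linear` link
($p_i = \min(\max(L_i, 0), 1)$) is provided for literal fidelity to the
printed formula. The link is configurable and recorded in the probability
map's provenance. Two overrides follow the clinical definitions: GTV
voxels are residual tumour and get $p = 1$; CSF voxels get $p = 0$ because
the model was never validated there. The map is masked to the CTV: outside
it the probability is `NaN`, so accidental use fails loudly rather than
silently.

CTV voxels that fall outside the perfusion field of view have no model
input; they receive probability 0 (with a warning), which maps to the safe
60 Gy base dose downstream — the conservative choice when the imaging does
not support a boost.

## Prescription and inverse prescription

Probability maps to dose linearly between `dMinGy = 60` (standard of care)
and `dMaxGy = 80` (the maximum tolerated dose in dose-escalation trials):

$$D^{\mathrm{rx}}_i = D_{\min} + (D_{\max}-D_{\min})\,p_i .$$

The PTV ring outside the CTV (setup margin) is prescribed the base dose.
The inverse prescription $D_{\max} - D^{\mathrm{rx}}_i$ is provided because
clinical planning systems often cannot accept a heterogeneous target dose
directly; assigning the inverse map to a mock "pretreated" plan coerces
them. The surrogate optimizer here does not need the trick, but the
operation is part of the workflow's interface. Fractionation (30 daily
fractions) is metadata only: all doses are physical total dose, which is
also what the TCP model's radiosensitivity refers to.

## The surrogate optimizer

The clinical study used a commercial VMAT system, which cannot be
reproduced on a desktop. The package's `optimizePlan()` is a deliberately
transparent stand-in — **the major simplification in this package**. The
delivered dose is modelled as $D = K u$: a non-negative latent
fluence-like field $u$ convolved with an isotropic Gaussian point-spread
function (default FWHM 5 mm, the leaf width of a typical MLC). This
preserves the structure of the planning problem — a smoothness-limited fit
to a heterogeneous prescription under constraints — while dropping the
machine model (arcs, leaf sequencing, depth dose, tissue densities).

The objective is a weighted sum of one-sided quadratic penalties:

* squared deviation from the prescription inside the PTV (weight 1);
* under-dose penalties against minimum-dose targets of 76.8 Gy (GTV),
  61.2 Gy (CTV) and 60.6 Gy (PTV), and an over-dose penalty against
  77.5 Gy (PTV), each with weight 10;
* organ-at-risk penalties (weight 100) against the limit table below;
* a quadratic falloff penalty (weight 0.01) outside the PTV beyond 10 mm.

Weights mirror treatment-planning priorities (hard clinical goals dominate
the soft fit term) and are exposed in `SurrogateBeamModel`. Optimization
is projected gradient descent: the latent field starts at the prescription
(zero outside the PTV), steps are halved whenever the objective would
increase and grown 10% after accepted steps, so the objective trace is
non-increasing by construction. Convergence is declared when the relative
objective change drops below `tol` (default 1e-6); if the iteration cap
(default 400) is hit first, the plan is returned with
`converged = FALSE` rather than an error, since a usable dose distribution
exists at every iterate. In `standard` mode the target dose is uniform
60 Gy and the GTV/CTV minimum-dose boost targets collapse to the PTV
coverage goal — a uniform plan prescribes no boost, and keeping the
76.8 Gy GTV target would smuggle dose painting into the comparison arm.

Organ-at-risk limits default to EORTC-style values: mean brain dose
< 45 Gy; maximum dose < 54 Gy for brainstem, chiasm and optic nerves,
< 10 Gy for lenses, < 50 Gy for retinas. The brain mean-dose limit is
reported inconsistently in the clinical literature this workflow follows
(45 Gy in one place, 50 Gy in another); the package defaults to the
stricter 45 Gy and the table is fully configurable. Where an OAR
geometrically intersects the PTV the 60 Gy base prescription conflicts
with the limit and the optimizer settles on a weighted compromise a few
Gy above it — the same behaviour clinical plans exhibit.

## Evaluation metrics

**Quality factor.** Conformity is scored as
$\mathrm{QF} = 100 - \frac{100}{n}\sum_i |D^{\mathrm{plan}}_i -
D^{\mathrm{rx}}_i| / D^{\mathrm{rx}}_i$ over a structure: 100 minus the
mean absolute relative deviation, in percent, so an ideal plan scores
exactly 100. (Some statements of this formula omit the explicit factor
100 on the mean while still quoting QF in percent with an ideal value of
100; the package follows the percent-scale convention of the dose-painting
conformity literature.) The planning goal adopted for dose painting is
QF ≥ 95 % within the GTV.

**DVH metrics.** Cumulative DVHs use uniform dose bins (default 0.1 Gy).
`Dx%` — the dose received by at least x% of the structure — is the
(100−x)th percentile of voxel doses with linear interpolation between
order statistics (type-7); whether clinical DVH engines interpolate or
take the nearest voxel is not standardized, so the deterministic
interpolating choice is made once and oracle-tested. `VxGy` is the percent
of structure voxels at or above x Gy.

**Tumour control probability.** The Poisson-type model
$\mathrm{TCP} = \exp(-C \sum_i p_i e^{-\alpha D_i})$ uses
$\alpha = 0.12\ \mathrm{Gy}^{-1}$ from historical dose-escalation studies.
$C$ is calibrated by `calibrateC()` so the cohort-mean CTV TCP of the
standard plans equals the 27 % one-year progression-free survival of
standard of care; since mean TCP is continuous and strictly decreasing in
$C$, bisection on $\log C$ over $C \in [10^{-8}, 10^{3}]$ converges to the
unique solution (tolerance 1e-6 on the achieved TCP). The default
`cConstant = 0.032` is the value such a calibration produces on the
original patient cohort. $D_i$ is the *planned* dose by default — the
model converts a deliverable dose distribution into a control probability;
passing a prescription evaluates the intended dose instead, and both uses
appear in the literature.

**Statistics.** Paired plan comparisons use the Wilcoxon matched-pairs
signed-rank test, two-sided, with zero differences dropped: the exact
signed-rank null for up to 25 non-zero pairs (untied), the tie-corrected
normal approximation otherwise, and a flagged degenerate result with
$p = 1$ when all differences vanish. No multiplicity correction is
applied, matching how such planning studies report raw p-values.

## Margins and structures

CTV = GTV + 15 mm, clipped to the brain mask; PTV = CTV + 3 mm, not
clipped, because the setup margin models positioning uncertainty rather
than anatomy (whether clinical PTVs are clipped at the surface varies by
centre; no clip is the package default). Expansion is an exact
anisotropy-aware Euclidean distance transform in physical mm thresholded
at the margin, with the barrier applied as a post-hoc clip — the common
treatment-planning behaviour; geodesic (obstacle-avoiding) expansion is a
possible extension. "Anatomical boundaries" reduce to the brain mask
because phantoms have no falx or tentorium. All grids use 0-based voxel
indices with physical position `origin + index * spacing` at voxel
centres, converted at the NIfTI boundary.

## The phantom generator

`generatePhantom()` emulates the co-registered, 1.2 mm isotropic inputs of
the study population: a 96³ grid; a brain ellipsoid (semi-axes 50 × 62 ×
48 mm) with a thin skull shell; two ellipsoidal ventricles labelled CSF; a
spherical GTV (default radius 10 mm, offset from centre so margins
interact with the brain boundary); geometric OARs (brainstem cylinder,
chiasm box, optic-nerve cylinders, lens and retina spheres), pairwise
disjoint and clear of the GTV; and an axial field-of-view slab covering
the GTV ± 30 mm, mimicking restricted perfusion coverage.

The ground-truth infiltration field decays exponentially with distance $d$
from the GTV surface, $p = e^{-d/\lambda}(1+\epsilon)$ with decay length
$\lambda = 10$ mm — a scale consistent with the 15 mm clinical CTV margin
for microscopic spread — modulated by a smooth perturbation $\epsilon$
(Gaussian-filtered white noise, kernel sd 6 mm, amplitude 0.15) so that
prescriptions are spatially non-trivial without destroying the monotone
decay. The field is clamped to $[10^{-5}, 1-10^{-5}]$ before the
GTV/CSF overrides: the infinitesimal margin keeps the logistic inverse
finite, which is what lets the zero-noise inversion roundtrip close to
floating-point precision. ADC and rCBF maps are then *constructed by
inverting the infiltration model*: the noiseless predictor
$L = \mathrm{link}^{-1}(p)$ is split between the two maps by
`mixingFraction` (default 0.5), and independent Gaussian noise (default sd
0.1, roughly 10 % of a standardized unit) is added per voxel. With zero
noise, the probability stage reproduces `pTrue` exactly outside the
overrides — a strong self-consistency check exercised in the tests.

Cohorts jitter the GTV radius (±2 mm) and centre (±5 mm per axis) with
deterministic sub-seeds derived from `(seed, case index)`, so a cohort is
reproducible and independent of generation order.

What the phantom does *not* emulate: MR physics (bias fields, distortion,
partial volume), registration error, DSC time-series artefacts, realistic
anatomy, or any spatial correlation between true infiltration and
anatomy beyond distance-to-GTV. Consequently, passing tests demonstrate
the correctness and internal consistency of the computational pipeline —
not that the infiltration model predicts recurrence in patients, which
only clinical validation can show.

## Pipeline defaults for phantom runs

Phantom ADC/rCBF maps are generated in standardized units by construction,
so `runCase()` defaults to field-of-view restriction only;
reference-region normalization, bilateral smoothing (defaults: spatial sd
2 mm at 1.2 mm resolution, range sd 0.5 in standardized units — values
chosen for light edge-preserving smoothing, as the clinical preprocessing
does not publish its filter parameters) and standardization are available
for externally supplied maps. Re-standardizing a phantom map would break
the calibrated link between the maps and the ground truth. Standardization
uses the population (÷N) standard deviation — a fixed, documented choice —
over brain ∩ FOV ∖ CSF by default, since the population over which the
source model standardized is not published; the mask is configurable.

## Problem sizes and determinism

The full-scale configuration is 96³ voxels at 1.2 mm with a 400-iteration
optimizer budget. The test suite exercises the same code paths at 48³ /
2.4 mm with 40–80 iterations, which keeps the complete suite within a few
minutes while leaving every algorithmic branch identical; the acceptance
script runs the surrogate optimizer once at full scale. All randomness
flows from explicit integer seeds through R's RNG; reruns with one seed
reproduce all outputs bit-identically on one platform.

## Known limitations

* The fluence-convolution optimizer is not a deliverability model: no
  MLC sequencing, arc geometry, depth dose or heterogeneity corrections.
  Absolute dose metrics from it characterize the surrogate, not a linac.
* Cohort-level clinical results from the original 17-patient study are
  not reproducible here; phantom cohorts support methodological and
  self-consistency claims only.
* TCP values are relative decision aids calibrated to one survival
  statistic; they are not absolute outcome predictions.
* Rigid registration and perfusion-map derivation from raw DSC data are
  out of scope; inputs are assumed co-registered.

## A minimal run

```{r example}
library(DosePaintR)
cfg <- defaultRunConfig(seed = 1L)
res <- runCase(cfg, outDir = "case01")
subset(res$comparison, structure == "GTV")
res$constraintsDp
```
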