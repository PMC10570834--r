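---
title: "Evaluating and comparing radiotherapy plans from DVH data"
author: "radcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating and comparing radiotherapy plans from DVH data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radcomp)
```

## The problem

Whole-breast radiotherapy is prescribed either conventionally fractionated
(CF: 50 Gy in 25 fractions of 2 Gy) or hypofractionated (HF: 42.56 Gy in 16
fractions of 2.66 Gy). Because the prescriptions differ, raw dosimetric
quantities (Dmean, Dmax, ...) are not comparable across arms; a fair
comparison needs fractionation-corrected radiobiological endpoints. radcomp
evaluates each patient's plan from its dose–volume histograms (DVHs) and
compares two patient cohorts quantity by quantity.

All computations consume a per-structure *differential* DVH: dose bins with
the fraction of the structure volume in each bin. Zero-width "delta" bins
represent point masses, which is how exactly uniform irradiation is encoded
(`uniform_dvh()`). Within a positive-width bin, dose is attributed to the
bin center for moment-type quantities, while Dx% and V_RI interpolate
linearly on the cumulative curve between bin edges; under this convention
splitting a bin in half changes nothing, so results are insensitive to the
export bin width (tested down to 1e-9 at matched bin-center dose, and to
1e-3 relative against a 20 000-voxel list at 0.01 Gy bins).

## Dosimetric indices

* **Homogeneity index**: `HI = (D2% − D98%) / prescription`. 0 is ideal.
  On a cumulative-curve plateau, Dx% returns the highest dose attaining the
  requested volume fraction — the "minimum dose received by x% of the
  volume" reading.
* **Conformity index**:
  `CI = (V_RI of PTV)² / (100 · Σ_structures V_RI)`, with every V a
  percentage of the structure's own volume and the PTV included in the
  sum — the only normalization for which the ideal case (100% PTV
  coverage, nothing else at the isodose) gives exactly 1. The reference
  isodose defaults to 95% of prescription (47.5 Gy CF, 40.43 Gy HF).

  The chest wall is excluded from the denominator by default: in breast
  plans it overlaps the irradiated volume and is deliberately carried to
  near-prescription dose, so counting it would pin CI near 0.5 for any
  clinically conformal plan, contradicting the 0.95+ values such plans
  actually score. Pass `exclude = character(0)` to count every structure.

## Radiobiological models

All endpoints first convert each bin's total dose `D_i` to the
2 Gy-per-fraction equivalent under the linear-quadratic model,

EQD_i = D_i · (α/β + D_i/n_f) / (α/β + 2),

assuming every voxel is treated in all `n_f` fractions (the only reading
consistent with a single plan-level fraction number). α/β = 4 Gy is used
for breast target, heart and lung.

* **EUD** (Niemierko): the generalized volume-weighted mean
  `(Σ v_i EQD_i^a)^(1/a)` with a = −7.2 for the breast target. Negative
  `a` makes cold spots dominate; a zero-dose bin drives the limit to 0,
  which is returned with a warning (`dose_floor` clamps cold bins for
  users who want a robust value). Evaluation is in log space, so extreme
  exponents (|a| ~ 100) stay stable; note that in the a → −∞ limit the
  value approaches `min(EQD) · w_min^(1/a⁻¹)`-style offsets, i.e. it only
  pins to the minimum when the coldest component carries appreciable
  volume.
* **TCP** (Poisson linear-quadratic): voxel-wise control probability
  `exp(−exp(eγ − (EQD_i/D50)(eγ − ln ln 2)))` aggregated as a
  volume-weighted geometric product (computed as a log-sum). `e` is
  Euler's number multiplying γ = 1.3; D50 = 30.89 Gy. A uniform EQD at
  D50 gives exactly 0.5 by construction.
* **NTCP** (Lyman–Kutcher–Burman): the DVH is reduced to
  `Deff = (Σ v_i EQD_i^{1/n})^n` (the Kutcher–Burman generalized mean,
  the only exponent placement for which uniform dose returns itself),
  then `NTCP = Φ((Deff − D50)/(m·D50))` with Φ the standard normal CDF —
  the only orientation of the probit integral that gives NTCP(D50) = 0.5
  and NTCP increasing in dose. Heart: D50 = 48 Gy, m = 0.1, n = 0.35;
  lung: D50 = 37.6 Gy, m = 0.35, n = 0.87.

Parameters ship in `extdata/tissue_parameters.yaml` and every value can be
overridden per run (`read_tissue_parameters()`).

Per study convention, EUD and TCP are computed for the PTV only, NTCP for
the heart and each lung; spinal cord and contralateral breast are ingested
and volume-reported but get no dose-response endpoint.

## Cohort comparison

`compare_cohorts()` reports mean ± sample SD per arm and a two-sided
independent two-sample t-test per quantity, pooled-variance (Student) by
default — the classical reading of "independent sample t-test" — with
Welch behind a flag. The sign convention is `t = (CF − HF)/SE`. Zero
pooled variance is resolved explicitly (equal means: t = 0, p = 1;
unequal: t = ±Inf, p = 0). Significance is declared at p < 0.05 with no
multiple-testing correction, and the report row order is fixed: volumes,
CI, HI, PTV dose statistics, EUD/TCP/NTCP, V-level coverages.

## What the synthetic generator emulates

`generate_cohort()` produces arms of 19 (CF) and 9 (HF) patients by
default. For each structure of each patient it draws an absolute volume
(truncated Gaussian matched to observed whole-breast cohort means: PTV
673 ± 206 cm³, heart 490 ± 79 cm³ CF, etc.), a patient-level mean dose
(truncated Gaussian around a structure-specific fraction of prescription),
and a patient-level heterogeneity SD (lognormal jitter), then lays the DVH
down as the bin masses of a Gaussian truncated at 0 Gy on a 0.1 Gy grid. A
`bimodal_cold_spot` shape adds a low-dose mixture component to exercise
the negative-exponent EUD sensitivity.

The dose-model defaults are tuning constants, not measured values: target
and chest wall at 1.03 × prescription with ~1–1.5 Gy spread, ipsilateral
lung at 0.35 × prescription (chosen by inverting the LKB model so lung
NTCP lands in the few-percent range clinical plans report), heart at 0.05
and contralateral structures at ~0.03. Between-patient spread parameters
exist so that arm comparisons have genuine sampling variance — without
them every t-test would be degenerate. With these defaults the pipeline
reproduces the expected qualitative orderings: TCP(CF) > TCP(HF), lung
NTCP lower under HF, EUD higher for CF in Gy but higher for HF relative
to prescription, heart NTCP ≈ 0 in both arms.

What the generator does **not** emulate: spatial anatomy (DVHs are drawn
independently per structure, so inter-structure dose correlations within a
patient are absent), planning-system constraints, setup error, or
non-Gaussian DVH shapes beyond the cold-spot mixture. Passing tests
therefore certify the computational pipeline and its statistical
machinery, not clinical dose distributions.

Reproducibility: each patient is generated from a substream seeded by
`(cohort seed, patient index)`, so a patient is identical regardless of
cohort size or generation order, and the caller's RNG state is untouched.

## Numerical and design notes

* Differential ↔ cumulative conversion is exact bookkeeping
  (`cumsum`/`diff`), bijective to 1e-12.
* Quantile queries at a delta bin return that dose exactly; V queries at
  exactly a bin edge are inclusive (dose ≥ RI).
* Degenerate inputs are explicit errors: empty DVHs, non-contiguous CSV
  bins, a plan with nothing at the reference isodose, arms with fewer than
  two readable patients. Corrupt patient files are skipped with a warning
  and counted.
* Problem sizes used in the shipped tests: 20 000-voxel oracle
  comparisons, 500 null replicates for type-I-error calibration of the
  arm comparison (observed rejection rate must lie in [0.02, 0.09]), 200
  replicates for the HI power check (1 Gy vs 3 Gy target heterogeneity at
  n = 19 vs 9, > 80% detection), 200-patient cohorts for volume-model
  checks.

## Limitations

* Only the classical pooled/Welch t-test is provided — no non-parametric
  alternatives, equivalence testing, or TCP/NTCP confidence intervals.
* No alternative TCP/NTCP models (logistic, relative seriality) and no
  time/repopulation factors in the LQ conversion.
* DICOM-RT ingestion is an adapter interface (`read_patient_dicom()`)
  validating a caller-supplied reader; the package itself parses only the
  CSV DVH exchange format.
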