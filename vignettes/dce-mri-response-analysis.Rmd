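---
title: "Tracer-kinetic DCE-MRI analysis for early response prediction in HCC"
author: "dcekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracer-kinetic DCE-MRI analysis for early response prediction in HCC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcekit)
```

## The problem

Hepatocellular carcinoma (HCC) at intermediate/advanced stage is commonly
treated with transcatheter arterial chemoembolization (TACE), increasingly
followed by the multi-kinase inhibitor sorafenib. Morphological follow-up
(mRECIST on dynamic CT/MRI) takes a month or more to declare a response;
quantitative dynamic contrast-enhanced MRI (DCE-MRI) may anticipate that
verdict within days, sparing non-responding patients an expensive and
toxic therapy. `dcekit` implements the full analysis chain for this
question: signal-to-concentration conversion, one-compartment tracer-kinetic
fitting, mRECIST grouping, cutoff-based early prediction with diagnostic
metrics, and the accompanying nonparametric statistics — plus a synthetic
cohort generator so that every stage can be validated end to end without
patient data.

## Acquisition model

The sampling scheme is a burst-phase liver protocol: bursts of 5 frames over
30 s (one frame per 6 s), acquired pre-contrast, at the hepatic
arterial-dominant phase, and at nominal post-injection delays of 60, 120,
180, 240, 330, 420, 510 and 600 s — 50 frames in all. `acq_schedule()`
anchors time 0 at contrast injection, so the pre-contrast burst carries
negative frame times and baseline frames identify themselves. The absolute
timing of the arterial-dominant burst is set per patient by a monitoring
scan in practice and is not protocol-fixed; the packaged default places it
at 20–50 s so that a bolus arriving at the default 20 s peaks inside it.
Frame times are burst midpoints (3, 9, 15, 21, 27 s into each burst).

## From signal to concentration

Tracer concentration is approximated by relative signal enhancement,

$$C(t) = \frac{S(t)}{S_0} - 1,$$

with $S_0$ the arithmetic mean of the pre-contrast frames (averaging all
five reduces baseline noise; the estimator is a documented choice). No
relaxivity calibration is applied: the analysis assumes enhancement is
proportional to concentration, which is adequate for the moderate
concentrations of a standard 0.025 mmol/kg hepatocyte-specific agent but is
an approximation, and all concentration-like quantities in this package are
in enhancement units. The conversion is invariant to global signal scaling,
and a baseline at or below a configurable floor is a hard error rather than
a silent division blow-up.

Arterial input functions are taken from aortic ROIs. `semi_auto_aif()`
emulates semi-automatic selection over several aortic slices: candidate
curves whose peak falls below a configurable fraction (default 0.5) of the
largest candidate peak — partial-volume or mis-placed slices — are excluded
and the survivors averaged. The exclusion rule is this package's stated
convention; "semi-automatic" selection is not otherwise standardized.
Whole-blood enhancement is converted to plasma concentration by
$C_p = C_b / (1 - \mathrm{Hct})$ with a fixed hematocrit of 0.45.

## The kinetic model

A one-compartment Tofts model describes the tissue curve:

$$C_t(t) = K^{trans} \int_0^t C_p(\tau)\,
  e^{-\frac{K^{trans}}{DV}(t-\tau)}\,d\tau$$

with two parameters, reported in the field's units: the transfer constant
$K^{trans}$ (ml/100 ml/min) and the distribution volume $DV$ (ml/100 ml).
With a hepatocyte-specific agent, $DV$ aggregates plasma, interstitial and
intracellular space, and $K^{trans}$ mixes perfusion, permeability-surface
area and cellular uptake; no separate plasma-volume term is modelled.
Internally the solver works in per-second, fractional-volume units.

`tofts_forward()` treats $C_p$ as piecewise linear between samples and
evaluates the convolution integral interval by interval in closed form — it
is exact for piecewise-linear inputs, so its only approximation error is
the linear interpolation of the AIF itself. The test suite checks it
against brute-force fine-grid quadrature (relative error $< 10^{-4}$ over
the clinically reliable parameter range) and against the analytic
two-exponential solution for a mono-exponential input.

`fit_tofts()` estimates both parameters by bounded Levenberg–Marquardt
least squares over $K^{trans} \in [0, 1000]$, $DV \in (0, 100]$, fitting
all 50 frames jointly (an alternative would average the 5 frames per burst;
joint fitting preserves the intra-burst information and is the default).
The optimizer is initialized from a linearized integral-equation solve
(the compartment ODE integrates to a model linear in $K^{trans}$ and
$K^{trans}/DV$) and restarted from $K^{trans} \times 0.3$ and $\times 3$ to
guard against local minima under sparse burst sampling; convergence
tolerance is $10^{-8}$ and the convergence flag is honest. Noiseless
curves on the burst schedule are recovered to well under 1% across a wide
parameter grid.

### Identifiability and the DV quality gate

When $K^{trans}$ is very small, the washout time constant $DV/K^{trans}$
far exceeds the 600-s window: the curve never approaches saturation and
carries almost no information about $DV$. The least-squares surface then
has a flat ridge and the $DV$ estimate can wander to its bounds — exactly
the instability clinicians observe in poorly perfused, largely necrotic
lesions. `fit_tofts()` therefore reports asymptotic standard errors from
the Gauss–Newton approximation, and `fit_cohort()` withholds $DV$
(reports `NA`) when its relative standard error exceeds 50% — the usual
"parameter determined to better than a factor of ~1.5" reporting rule.
About 2% of lesions are affected at the default simulation settings. The
same mechanism makes very large fitted $K^{trans}$ values (> 100
ml/100 ml/min) unreliable at 6-s sampling; they are reported as fitted but
should be interpreted with care.

### Model-free plasma flow

`plasma_flow_deconvolution()` supports ROI placement with a plasma-flow
estimate that makes no compartmental assumption: the convolution relation
$C_t = PF \cdot (C_p \ast R)$ is discretized on a uniform grid and
inverted by truncated-SVD regularization, discarding singular values below
`reg` times the largest (default 0.15 for sparse clinical sampling; dense
grids can use far less). $PF$ is the peak of the recovered impulse
response. The algorithm choice (TSVD rather than, e.g., Tikhonov) is an
implementation decision of this package.

## Response classification and early prediction

`mrecist_classify()` implements the four modified-RECIST definitions for
viable (arterially enhancing) tumor in their original four-rule form, with inclusive
boundaries ("at least a 30% decrease" is PR, "an increase of at least 20%"
over the nadir is PD, PD evaluated first) and without the consensus
guideline's additional minimum-absolute-increase clause. Responders are CR
or PR at final follow-up; non-responders SD or PD. The rules are invariant
to uniform diameter rescaling, which the suite asserts.

Early prediction calls a lesion a future responder when its $DV$ at a
given timepoint lies at or below a cutoff. The constructive rule —
responder mean plus two population SDs, `cutoff_mean_plus_2sd()` — is
exposed, but the packaged default cutoffs are the worked example's reference
values (40, 30, 17 ml/100 ml for pre-TACE, day 3, day 10). The two
disagree slightly (the day-10 responder statistics imply 18.0, not 17);
reproducing the reference table takes precedence, and the rule remains
available for new data. `diagnostic_metrics()` computes sensitivity,
specificity, PPV and NPV from exact fractions, plus the clinical utility
indexes $CUI^+ = \text{sens} \times PPV$ and
$CUI^- = \text{spec} \times NPV$; zero-denominator metrics are reported as
explicitly undefined rather than NaN — small cohorts do hit these cells.
Percentages are formatted with half-up rounding (87.5% prints as 88%),
indexes to three decimals.

## Statistics

The cohorts this analysis serves are small (8 responder vs 13 non-responder
lesions), so the package computes exact small-sample p-values by
enumeration rather than trusting asymptotics:

* `friedman_exact()` — within-lesion comparison across the three
  timepoints; mid-ranks for ties, tie-robust (Conover-form) chi-square
  statistic, exact permutation null over all $(k!)^n$ within-row
  arrangements via dynamic programming for $n \le 8$ rows, chi-square
  approximation above.
* `mann_whitney_u()` — responder vs non-responder comparison; exact
  enumeration of the U distribution for $n_x + n_y \le 25$ without ties,
  tie-corrected normal approximation otherwise (no continuity correction,
  so identical groups give p = 1 by symmetry).
* `spearman_rank()` — correlation of kinetic parameters with angiogenesis
  factors (Ang2, VEGF, c-KIT); exact permutation p for $n \le 9$,
  t-approximation above. Patient-level factor values are duplicated across
  that patient's lesions, mirroring how such data are analyzed in practice;
  the resulting pseudo-replication anti-conservatively shrinks p-values and
  is documented rather than hidden.
* `anova_across_time()` — repeated-measures ANOVA (time and group × time)
  for the angiogenesis factors, from sequential sums of squares with the
  within-subject residual as the error term; degenerate zero-variance
  inputs return F = 0 (no effect) or F = ∞ with p → 0 (pure effect)
  instead of NaN.

Every exact routine is validated against an independent brute-force
enumeration oracle in the test suite, and against the base-R
implementations where they overlap. Descriptive summaries default to the
population (divide-by-n) SD convention, which is what makes the
worked example's reported interval SD (2.0 days) reproduce; the sample
convention is available everywhere. No multiple-testing correction is
applied by default, matching the analysis style the package reproduces.

## The synthetic cohort generator

`generate_cohort()` exists so that the full pipeline can be exercised and
calibrated with known ground truth. What it emulates:

* cohort structure: configurable patients × (at most 2) lesions, default
  11 × 2 capped at 21; per-lesion responder probability 8/21; final mRECIST
  categories drawn consistently with the group (CR:PR as 5:3, SD:PD as
  11:2);
* kinetic ground truth: per-group, per-timepoint truncated-normal draws
  whose nominal means/SDs are the reference group statistics (responder DV
  28.4 ± 12.4 → 14.2 ± 7.0 → 8.6 ± 4.7 ml/100 ml, etc.), truncated at the
  physical bounds (DV in (0, 100], K^trans in [0, 1000]). Truncation
  shifts the realized moments — dramatically so for the K^trans cells,
  whose nominal coefficients of variation exceed 1 and are unattainable by
  any zero-truncated normal — so validation compares generated samples to
  the analytic truncated-normal moments (`truncnorm_moments()`), not to
  the nominal values;
* shared physiology: a Gaussian-copula correlation (default 0.3) between
  the two lesions of a patient — unstated in the source material, made
  explicit here;
* the measurement: a deterministic population AIF (gamma-variate first
  pass peaking ~10 s after the default 20-s arrival, blood peak
  enhancement 3.0, plus a recirculation tail), hematocrit-corrected,
  driving `tofts_forward()`; signals reconstructed as $S = S_0(1 + C)$
  with $S_0 = 100$ and Gaussian noise of SD $S_0/\mathrm{SNR}$, default
  SNR 40 — a deliberate choice for whole-lesion ROI-mean curves, which
  average many voxels and are far cleaner than single-voxel data;
* covariates: Ang2 generated rank-correlated with patient-level DV
  (target Spearman 0.6 via the copula transform), VEGF and c-KIT
  independent of the kinetics.

What it does **not** emulate: anatomy and partial-volume effects, motion,
scanner drift, arterial dispersion/delay differences between aorta and
lesion, non-Gaussian (Rician) magnitude noise at low SNR, and any
relationship between lesion size and kinetics. Passing end-to-end tests on
this generator therefore demonstrates that the estimation and statistics
machinery is correct and calibrated under the model's own assumptions, not
that the model is adequate for any particular scanner or patient.

Everything is reproducible: a `cohort_spec(seed = )` fixes all draws, and
identical specs produce byte-identical cohorts.

## Problem sizes used in validation

The packaged validation suites use: a 5 × 5 noiseless parameter grid and 50
noisy replicates at baseline SNR 20 for recovery; 100 random parameter
draws against the quadrature oracle; a 500-lesion simulated cohort
(250 patients) for the end-to-end group-mean recovery and Friedman
rejection check; exhaustive enumeration oracles up to n = 6; and 2,000
null simulations at the study's 8-vs-13 group sizes to confirm the exact
Mann–Whitney test's size stays near 5% ([0.03, 0.07]). These sizes were
chosen to make sampling error small relative to the tolerances while
keeping the suite quick on a laptop.

## Worked example

```{r example, eval = FALSE}
library(dcekit)

# the packaged 11-patient / 21-lesion study table
ds <- load_study_table()
describe_study(ds)
group_responders(ds$lesions$outcome_final)

# a synthetic study: simulate, fit, analyze
co <- generate_cohort(cohort_spec(seed = 1))
co$dataset$kinetics <- fit_cohort(co)
summarize_groups(co$dataset, "dv")
res <- analyze_study(co$dataset)
res$friedman$dv_responder
res$prediction$day10
```

## Known limitations

* Relative enhancement is a linear concentration proxy; no T1 mapping,
  B1 or inflow correction is attempted (out of scope by design).
* $DV$ and $K^{trans}$ with a hepatocyte-specific agent are composite
  quantities; the package computes them faithfully but their physiological
  reading is agent-dependent.
* The deconvolution is ROI-oriented; no voxelwise whole-image parameter
  maps are produced.
* Lesion clustering within patients is handled descriptively (mixed-outcome
  patients are reported), not by mixed-effects modelling.
* Survival endpoints are out of scope.
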