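# dcekit

Tracer-kinetic analysis of dynamic contrast-enhanced MRI (DCE-MRI) for
early prediction of hepatocellular carcinoma (HCC) response to
transcatheter arterial chemoembolization (TACE) followed by sorafenib.

Morphological response assessment (mRECIST) needs a month or more of
follow-up. Quantitative DCE-MRI at 3 and 10 days after TACE can anticipate
it: in responding lesions the contrast-agent distribution volume falls
progressively, while in non-responders it recovers. `dcekit` implements
the complete analysis chain for radiologists and imaging scientists working
on this question, together with a synthetic-cohort generator that makes
every stage testable end to end without patient data.

## What it computes

Tissue concentration is approximated by relative enhancement
`C(t) = S(t)/S0 − 1`, arterial blood is converted to plasma with a fixed
hematocrit (`Cp = Cb/(1 − Hct)`, Hct = 0.45), and each lesion ROI is fitted
with the one-compartment Tofts model

    Ct(t) = Ktrans ∫₀ᵗ Cp(τ) · exp(−(Ktrans/DV)(t − τ)) dτ

yielding the transfer constant **Ktrans** (ml/100 ml/min) and the
distribution volume **DV** (ml/100 ml). The convolution is evaluated in
closed form for a piecewise-linear AIF; fitting is bounded
Levenberg–Marquardt with a linearized-solve initialization and multistart.
Around the model sit:

* model-free plasma-flow estimation by truncated-SVD deconvolution (ROI
  placement aid);
* mRECIST classification (CR/PR/SD/PD on viable, arterially enhancing
  tumor) and responder (CR|PR) / non-responder (SD|PD) grouping;
* cutoff-based early prediction ("DV ≤ cutoff ⇒ future responder") with
  sensitivity, specificity, PPV, NPV and the clinical utility indexes
  CUI⁺ = sens × PPV, CUI⁻ = spec × NPV, plus the mean + 2 SD cutoff rule;
* exact small-sample statistics: Friedman across timepoints, Mann–Whitney
  between groups, Spearman correlation with angiogenesis factors
  (Ang2/VEGF/c-KIT), repeated-measures ANOVA — with enumeration-exact
  p-values at the cohort sizes this field actually has;
* a synthetic cohort generator emulating the burst-phase acquisition
  schedule (5 frames / 30 s per phase; pre-contrast, arterial-dominant,
  60–600 s) with configurable group kinetics, noise and correlations.

See the vignette (`vignettes/dce-mri-response-analysis.Rmd`) for the model
assumptions, parameter conventions, identifiability limits and design
decisions.

## Worked example

```r
library(dcekit)

# packaged 11-patient, 21-lesion study table
ds <- load_study_table()
str(describe_study(ds))
#> $ n_patients        : int 11
#> $ n_lesions         : int 21
#> $ size_mean_mm      : num 22.6      # mm, population SD 17.9
#> $ interval_mean_days: num 2.73      # MRI-to-TACE interval, SD 2.05
group_responders(ds$lesions$outcome_final)$by_category
#> CR PR SD PD
#>  5  3 11  2                         # responders 8, non-responders 13

# simulate a cohort, fit every lesion, summarize
co <- generate_cohort(cohort_spec(seed = 1))
co$dataset$kinetics <- fit_cohort(co)
summarize_groups(co$dataset, "dv")
#>           group timepoint  n mean    sd
#> 2 non_responder  pre_tace 14 33.2  6.63
#> 4 non_responder      day3 14 28.8 12.29
#> 6 non_responder     day10 14 29.2  7.28
#> 1     responder  pre_tace  7 29.0 11.35
#> 3     responder      day3  7 15.7  6.22
#> 5     responder     day10  7 10.5  3.62
```

The fitted group means show the expected pattern: responder DV falls
steadily across the three timepoints while non-responder DV rebounds by
day 10. The full analysis layer is one call away:

```r
res <- analyze_study(co$dataset)
res$friedman$dv_responder
#> <stat_result> Friedman (exact permutation): statistic = 5.4286,
#>   p = 0.08539 (exact)        # 7 complete responder lesions: underpowered,
#>                              # as a real 21-lesion pilot would be
res$prediction$day10          # cutoff-based early prediction report
```

A thin command-line wrapper over the same functions is provided at
`inst/cli/dcekit.R` (`simulate`, `fit`, `analyze`, `report` subcommands).

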