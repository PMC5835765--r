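# fcdsre

Quantitative analysis pipeline linking lesion volume in focal cortical
dysplasia (FCD) type II to sleep-related epilepsy (SRE: more than 90% of
a patient's seizures occur during sleep). The package is aimed at
epilepsy-imaging researchers who want a tested, reproducible
implementation of the full chain from segmentation label maps to
association tables:

- **Volumetry & normalization** — structure volumes from NIfTI label
  maps (voxel count × |det| of the affine's linear part), head-size
  correction `normalized = raw × mean(ICV) / ICV`, and `log10`
  transformation of the skewed lesion volumes.
- **Entropy-based dichotomization** — with `p` the fraction of lesions
  detected on the initial radiology report, the label entropy is
  `H(D) = −p log₂ p − (1−p) log₂(1−p)`; a threshold `T` splits `D` into
  `D₁ = {v < T}` and `D₂ = {v ≥ T}` and the search maximizes the
  information gain
  `Gain(D,T) = H(D) − (|D₁|/|D|)·H(D₁) − (|D₂|/|D|)·H(D₂)`
  over all midpoints between consecutive distinct volumes. Lesions below
  the optimal `T` are "small".
- **Association stage** — Fisher exact / Pearson / Yates 2×2 tests with
  an explicit dialect rule, Wilcoxon rank-sum, univariate screening at
  the 0.1 entry level, multivariable logistic regression with reference
  coding (frontal lobe as location reference; the small-lesion term is
  the adjusted odds ratio), ANCOVA on age/sex/ICV with a Bonferroni
  family of 3 (p < 0.017), and partial correlations.
- **Cohort reconstruction** — `paper_fixture()` deterministically builds
  a 77-patient cohort that jointly reproduces every published
  cross-tabulation (36/41 SRE split, 41 small / 34 large at 3,217 mm³,
  BOSD, location, subtype and subgroup cells), with a self-check
  asserted on every build.
- **Synthetic cohorts** — `simulate_cohort()` draws cohorts with known
  ground truth (log-normal volumes, volume-dependent report detection, a
  size effect on SRE odds) for recovery and calibration experiments via
  `recovery_experiment()`.

Everything is tibble-first and pipe-friendly; fitted objects support
`tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(fcdsre)

run <- run_pipeline(paper_fixture())
run
#> FCD lesion-size / SRE pipeline run
#>   threshold: T = 3217.00 mm^3 (gain 0.2902 bits, standard mode)
#>   classification: 41 small / 34 large / 2 unclassifiable
#>   size x SRE: p = 0.002806 (chi_square_pearson)
#>   adjusted small-lesion OR: 3.49 (95% CI 1.22-10.02), p = 0.0199
```

The gain search lands at 3,217 mm³, classifying 41 of the 75 measurable
lesions as small; the two radiologically invisible lesions are
unclassifiable and excluded from size analyses. Small lesions are
strongly over-represented in the SRE group:

```r
cross_tab(run$cohort[!is.na(run$cohort$size), ], size, sre)
#> 2x2 table: size x sre  (n = 75 )
#>       TRUE FALSE
#> small   25    16
#> large    9    25
#> row %:
#>       TRUE FALSE
#> small 61.0  39.0
#> large 26.5  73.5
```

61.0% of small lesions vs 26.5% of large lesions belong to SRE patients.
Because the source tables never state which 2×2 test produced a given
p-value, the pipeline reports all three dialects:

```r
run$tests$size_sre_dialects
#>   method             statistic    df p_value
#> 1 chi_square_pearson      8.93     1 0.00281
#> 2 chi_square_yates        7.59     1 0.00586
#> 3 fisher_exact           NA       NA 0.00485
```

and the adjusted small-lesion odds ratio (logistic model of SRE on age,
sex, size and location) is 3.49 with 95% CI 1.22–10.02. Published-table
layouts are available via `render_table(run, "table1")` …
`render_table(run, "table4")`, and `autoplot(run$threshold)` draws the
gain curve.

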