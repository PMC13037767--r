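# wearmiss

Diagnosing the likely missingness mechanism in repeated-measures wearable
sleep data.

## The problem

Nightly sleep summaries from consumer wearables (durations, in seconds, of
deep, light and REM sleep, time awake, plus an "unmeasurable" remainder) are
attractive for field studies because devices run for days without phones or
mains power — and notorious for missing data: batteries die, devices are
removed, sensors lose skin contact. Before imputing or modelling such data,
an analyst has to ask *why* nights are missing:

- **MCAR** (missing completely at random): missingness is unrelated to
  anything, observed or not. Complete-case analyses are then unbiased.
- **MAR** (missing at random): missingness depends only on *observed*
  variables (e.g. later nights are missing more often; employed participants
  miss more nights). Likelihood and multiple-imputation methods remain valid.
- **MNAR**: missingness depends on the unrecorded values themselves. No
  diagnostic based on the observed data can confirm this.

`wearmiss` packages a complete diagnostic workflow for five-night cohorts in
which a night is either fully recorded or fully absent:

1. **Pattern analysis** — enumerate the distinct five-night missingness
   patterns and tabulate missingness rates by night, site and covariates.
2. **Little's MCAR test** — implemented from its definition: EM estimation
   of a multivariate-normal mean μ and covariance Σ under incomplete data,
   then the pattern-wise statistic
   `d² = Σⱼ nⱼ (ȳⱼ − μ̂ⱼ)ᵀ Σ̂ⱼ⁻¹ (ȳⱼ − μ̂ⱼ)` compared to χ² with
   `Σⱼ pⱼ − p` degrees of freedom, where pattern *j* has *nⱼ* rows and *pⱼ*
   observed variables.
3. **Cluster-bootstrap random forest** — a missingness classifier whose
   per-tree bootstrap resamples *participants* (all five nights together),
   not nights, preserving within-subject correlation; the decision rule
   reads an out-of-bag AUC materially above 0.5 as covariate signal.
4. **GEE logistic regression** — a marginal model for the per-night
   missingness indicator with an exchangeable working correlation, robust
   (sandwich) standard errors, QIC-based working-structure comparison and
   forward variable selection.
5. **A mechanism verdict** — MCAR-not-rejected / consistent-with-MAR /
   inconclusive — combining the three lines of evidence, plus a cross-model
   agreement table.

Because real cohort data of this kind are rarely shareable, the package also
ships a **synthetic cohort generator** (`generate_sleep_data()`) emulating a
299-participant × 5-night actigraphy study with controllable MCAR / MAR /
MNAR deletion; its MAR defaults are the fitted missingness logit
`logit P(missing) = −1.8546 + 0.2554·night + 0.6671·employed`,
which yields ~30% overall missingness rising across nights.

## Worked example

Generate a cohort with strongly covariate-dependent (MAR) missingness and
run the whole pipeline:

```r
library(wearmiss)

cfg <- generator_config(seed = 2026,
  mar_coefficients = c(intercept = -1.8546, night = 0.2554, employed = 1.6))
ds  <- generate_sleep_data(cfg)
rep <- run_pipeline(ds, n_trees = 500)

missingness_rates(ds, by = "night_index")
#>   level   n_missing n_total fraction percent
#> 1 1              80     299    0.268      27
#> 2 2              87     299    0.291      29
#> 3 3             126     299    0.421      42
#> 4 4             135     299    0.452      45
#> 5 5             132     299    0.441      44
#> 6 overall       560    1495    0.375      37

rep$little
#> Little's MCAR test: d2 = 631.40, df = 499, p = 5.02e-05 (32 patterns)
rep$rf$oob_auc
#> [1] 0.775
tidy(rep$gee)
#> # A tibble: 4 x 8
#>   term        estimate std.error statistic  p.value odds.ratio ...
#> 1 (Intercept)    0.221    0.227      0.974 3.30e- 1     1.25
#> 2 night_index    0.286    0.0459     6.23  4.53e-10     1.33
#> 3 hr_present    -2.60     0.195    -13.4   1.02e-40     0.0742
#> 4 employed       1.72     0.141     12.2   2.30e-34     5.61

rep$diagnosis
#> mechanism verdict: consistent-with-MAR
```

Reading the output: missingness rises across nights and is far commoner for
employed participants; Little's test rejects MCAR (d² well above its 499
degrees of freedom); the cluster-bootstrap forest separates missing from
observed nights out of bag (AUC 0.775 ≫ 0.5); and forward selection retains
night index, prior-day heart-rate presence and employment with robust
p-values ≪ 0.05. All three lines of evidence point the same way, so the
verdict is *consistent-with-MAR* — the observed covariates predict
missingness, which licenses MAR-based imputation. With the default (fitted,
weaker) coefficients the covariate signal is still visible to both
classifiers, but Little's test — whose sensitivity here rests entirely on
the marginal covariate shifts between patterns — rejects far less often;
the methods vignette quantifies this.

Each result type has `tidy()` / `glance()` methods, `print()` methods, and
plots: `autoplot(enumerate_patterns(ds))` draws the observed/missing pattern
grid ordered by frequency; `plot_missingness_rates(ds)` the per-night rates.

A thin command-line front end over the same functions is installed at
`inst/cli/wearmiss.R`
(`Rscript wearmiss.R generate|patterns|little|fit-rf|fit-gee|run ...`).

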