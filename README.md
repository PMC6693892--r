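# quantsep

Does the brain encode *how many* things we see, or does it merely infer
number from correlated magnitudes — the area covered by the items, their
density, their summed surface? Answering this with fMRI requires a stimulus
design in which numerosity is decorrelated from non-numerical quantities, a
decoding protocol sensitive to fine-grained pattern information, and an
analysis that apportions pattern dissimilarity among *several* quantitative
dimensions simultaneously. `quantsep` implements that full analysis chain
for dot-array experiments, together with a population encoding-model
simulator that generates beta-like voxel patterns with task-dependent
attentional gain, so every stage of the pipeline can be validated by
parameter recovery before it touches real data.

## The design and the model

Stimuli are dot arrays living in a factorial quantity space: numerosity
*N* ∈ {6, 10, 17}, average item area *S* ∈ {0.04, 0.07, 0.12} vd², total
field area *TFA* ∈ {20, 44} vd² (18 conditions). Two quantities are derived,
total surface area *TSA = N·S* and density *D = N/TFA*, so the design is
orthogonal in (N, S, TFA) but only partially decorrelated from TSA and D.

The core estimator is a multiple-regression representational similarity
analysis. For each subject, task and region, the neural representational
dissimilarity matrix (RDM) collects correlation distances

d<sub>ij</sub> = 1 − corr(**p**<sub>i</sub>, **p**<sub>j</sub>)

between the voxel activity patterns **p** of every condition pair (153
pairs). Its vectorised upper triangle is regressed on five predictor RDMs,
one per dimension k, with entries |log v<sub>i</sub><sup>(k)</sup> − log
v<sub>j</sub><sup>(k)</sup>|:

z(d) ~ β₀ + β_N z(Δ log N) + β_S z(Δ log S) + β_TFA z(Δ log TFA) +
β_TSA z(Δ log TSA) + β_D z(Δ log D) + ε

Each β measures the pattern-dissimilarity variance *uniquely* explained by
that dimension over and above the others; variance inflation factors
VIF = 1/(1 − R²) diagnose the residual collinearity of the design.
Complementing the RSA, a leave-one-run-out linear SVM (C = 1) decodes each
pair of numerosities from 800 selected, voxel-wise mean-centered patterns,
and group inference uses paired t-tests with Cohen's d, repeated-measures
ANOVA with Greenhouse–Geisser correction, and a linear trend across the
ROI hierarchy.

## Worked example

Audit the reference stimulus grid:

```r
library(quantsep)
aud <- audit_design()
round(aud$vifs, 4)
#>             number      avg_item_area   total_field_area total_surface_area
#>             1.4674             1.2273             1.2092             1.3428
#>            density
#>             1.4543
round(aud$predictor_correlations["number", ], 3)
#>             number      avg_item_area   total_field_area total_surface_area
#>              1.000             -0.094             -0.076              0.313
#>            density
#>              0.419
```

All five VIFs stay below 1.5: despite number, TSA and density being
intrinsically linked, the factorial design leaves each dimension enough
unique variance for a stable regression.

Fit a psychometric function for the behavioral acuity pre-test and derive
the just-noticeable difference used to construct match stimuli:

```r
tr   <- comparison_trials("number")        # 432 comparisons vs 10 dots
resp <- simulate_observer(tr, sigma_true = 0.22, mu_true = 0.02, seed = 42)
fit  <- fit_psychometric(tr$log_ratio, resp)
fit
#> Cumulative-Gaussian psychometric fit
#>   mu    = -0.02411 (log-ratio units, PSE)
#>   sigma = 0.18957 (log-ratio units)
#>   JND   = 0.12786   Weber fraction = 0.1364
#>   logLik = -103.336 over 6 levels (432 trials), converged: TRUE
match_value(10, jnd(fit), "larger", round_integer = TRUE)
#> [1] 13
```

A match two JNDs above a 10-dot sample is 13 dots for this observer.

Run a small end-to-end synthetic experiment (6 subjects, an "early" and a
"higher" visual ROI preset; the higher preset has a built-in attentional
gain of 1.6 on its numerosity population during the number task):

```r
rep <- run_experiment(experiment_config(n_subjects = 6,
                                        rois = c("early", "higher")),
                      seed = 1)
rep
#> Mean numerosity decoding accuracy (+/- SEM):
#>     roi   task accuracy    sem
#>   early number    0.633 0.0199
#>  higher number    0.778 0.0167
#>   early   size    0.666 0.0155
#>  higher   size    0.648 0.0285
#> ...
rep$stats$beta_task_contrasts[
  rep$stats$beta_task_contrasts$dimension == "number", ]
#>      roi dimension         t df           p  cohens_d
#> 1  early    number -1.144597  5 0.304193497 -0.467280
#> 6 higher    number  5.272033  5 0.003266302  2.152299
```

The pipeline recovers the generative structure: decoding in the higher ROI
is better when number is attended (0.78 vs 0.65), and the RSA number beta
differs across tasks in the higher ROI (p = 0.003, d = 2.15) but not in
the early ROI — the attentional-amplification signature the analysis is
designed to detect.

## Layout

- `R/` — stimulus space, psychophysics, encoding-model simulator,
  decoding, RSA, group statistics, pipeline orchestration
- `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles
- `vignettes/quantity-separation.Rmd` — the methods vignette: model
  assumptions, parameter defaults, calibration choices, limitations
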