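---
title: "Separating numerosity from non-numerical quantities: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating numerosity from non-numerical quantities: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantsep)
```

This vignette is the package's own account of the models it implements, the
defaults it ships, and the reasoning behind the choices that were genuinely
open. It states no empirical result that the test suite does not itself
compute.

## 1. The quantity stimulus space

A dot array carries five quantitative dimensions: numerosity $N$, average
item area $S$ (vd²), total field area $TFA$ (vd²), and the derived total
surface area $TSA = N \cdot S$ and density $D = N/TFA$. `condition_grid()`
crosses three levels of $N$ (6, 10, 17), three of $S$ (0.04, 0.07, 0.12)
and two of $TFA$ (20, 44) into 18 conditions, ordered deterministically
($N$ slowest). The manipulated factors are mutually orthogonal by
construction; the derived dimensions are necessarily positively correlated
with $N$ (both are monotone in $N$ at fixed $S$, $TFA$), which is exactly
the confound structure the downstream regression is designed to resolve.

Two conventions deserve note:

* **Field areas are nominal.** The levels 20 and 44 vd² are treated as
  exact rather than as the areas of 5° and 7.5° diameter discs
  (19.63/44.18 vd²), because the derived densities then come out at the
  round values 0.30/0.50/0.85 and 0.14/0.23/0.39 dots/vd² that
  characterise the design. `condition_grid(exact_field_areas = TRUE)`
  switches to exact disc areas.
* **TSA is stored as $N \cdot S$.** Reference per-condition TSA tables for
  this design are slightly inconsistent with the nominal $S$ levels
  (e.g. 0.25 vs $6 \times 0.04 = 0.24$ vd², implying measured item areas
  near 0.0418/0.0703/0.1194 vd²). The grid keeps internal consistency
  ($TSA \equiv N\cdot S$); `dimension_correlation(..., tsa_values = )`
  accepts an explicit per-condition TSA table when a design must be
  audited against measured rather than nominal areas. Collinearity
  diagnostics computed from the nominal grid consequently differ from
  diagnostics computed from the (unknown) exact stimulus values by up to
  a few percent; the acceptance tests freeze the nominal-grid values,
  confirmed by a brute-force 153-pair oracle.

`render_dot_array()` realises a condition as non-overlapping black and
white discs (half and half, the extra dot black for odd $N$) placed by
uniform rejection sampling inside the virtual circle (centers restricted
to radius $R - r_i$; minimum edge gap 0.05°; at most 10,000 placement
attempts before an explicit failure naming the condition). Item areas are
heterogeneous — uniform on $S(1 \pm j)$ with jitter $j = 0.4$, then
rescaled so the mean is *exactly* $S$ — because a distributional form for
"heterogeneous" item sizes is not prescribed anywhere, and a rescaled
uniform keeps the condition-level quantities exact. `convex_hull_area()`
defaults to the hull of dot *centers* (the convention is not fixed by the
design; `boundary = "edge"` uses the outer dot boundary instead).

## 2. Psychophysics

The acuity pre-test presents 432 two-interval comparisons per task
(6 test/reference ratios × 6 item-area levels × 2 field areas × 2
presentation orders × 3 sessions) against a reference of 10 dots (number
task) or 0.1 vd² (size task). `fit_psychometric()` fits
$P(\text{"greater"} \mid x) = \Phi\!\left((x - \mu)/\sigma\right)$ on the
log-ratio axis $x = \log(\text{test}/\text{reference})$ by binomial
maximum likelihood. Choices:

* **Two parameters by default.** The toolbox originally used for such
  fits has many variants; a 2-parameter ML fit is the identifiable core.
  A *fixed* lapse rate can be supplied (`lapse =`), in which case the
  fitted probability is $\lambda/2 + (1-\lambda)\Phi$.
* **Optimiser.** Bounded L-BFGS-B on $(\mu, \log\sigma)$ from three
  dispersed starts, tolerance below $10^{-8}$ on the log-likelihood.
  The likelihood is written directly (not via `dbinom`) so that
  non-integer *expected* counts are valid input; the noiseless
  identifiability test exploits this.
* **JND and matches.** $JND = \Phi^{-1}(0.75)\,\sigma \approx
  0.6745\,\sigma$ (the 50%→75% distance). Match stimuli sit
  $\pm 2\,JND$ from the sample *on the log axis*,
  $v \cdot e^{\pm 2 JND}$, matching the axis of the psychometric fit;
  integer dot counts are rounded, and bumped one step away if rounding
  collides with the sample.

## 3. The encoding-model simulator

`simulate_betas()` generates the data structure the analysis consumes —
per subject, task, run and condition one beta-like pattern over a voxel
pool — from an explicit generative model:

$$\beta_{s,t,r,c,v} = b + \gamma_{t,d(v)}\, w_{d(v)} f_v(c) +
\varepsilon,\qquad \varepsilon \sim \mathcal N(0, \sigma_\text{noise}^2)
\text{ i.i.d.}$$

Each voxel belongs to one dimension-tuned sub-population $d(v)$ (or to an
untuned remainder). Numerosity voxels are log-Gaussian tuned,
$f_v(c) = \exp\{-(\log N_c - p_v)^2 / 2w^2\}$, with preferred values $p_v$
uniform on $[\log 6 - w, \log 17 + w]$ and width $w = 0.35$ log units —
log-scale tuning mirrors the log-distance predictors and the
ratio-dependence of numerosity perception. Voxels tuned to the extensive
magnitudes ($S$, $TFA$, $TSA$, $D$) are log-linear with random slope sign,
normalised to $[-1, 1]$ over the stimulus range, so their information is
carried by the *pattern*, not by the regional mean. Voxel counts per
sub-population are allocated by largest remainder (deterministic, so tests
can be exact); per-subject noise streams are derived from the master seed
by a congruential fan-out (`derive_seed()`), making cohorts extensible
without disturbing earlier subjects.

Three ROI presets are archetypes of the dorsal-stream hierarchy, not
anatomical claims: `"early"` is dominated by $TFA$/$TSA$/$D$ populations
with a weak numerosity population and *no* task modulation
($\gamma \equiv 1$); `"higher"` is numerosity-dominated with
$\gamma_{\text{number task, number}} = 1.6$ versus 1 in the size task;
`"intermediate"` sits between (gain 1.4). The item-size mixture is zero in
all presets — in this stimulus regime average item size is the dimension
for which pattern information is characteristically absent. Calibrated
default scale: baseline 1, weights 1, and $\sigma_\text{noise} = 6$,
chosen once so that the `"higher"` preset yields number-task pairwise
decoding in the 0.6–0.8 band with 800 selected voxels — the accuracy
regime in which the analysis is meant to operate. At these defaults the
50-replicate recovery harness in the acceptance suite attains power 1.0
for the number-beta task contrast with non-numerical rejection rates at
or below nominal.

**What the generator does and does not emulate.** It reproduces the
*statistical* structure the analysis assumes — condition-dependent mean
patterns, multiplicative feature-based attention, run-level noise — but
not spatial voxel correlations (an optional shared-noise factor is out of
scope), hemodynamics, GLM estimation, retinotopy, or between-subject
tuning heterogeneity (the population is fixed per dataset; subjects differ
by noise). Passing recovery tests therefore validates the *pipeline's
inferential logic*, not claims about real cortical populations.

## 4. Decoding

`pairwise_number_decoding()` follows the classification protocol exactly:
per subject, the 800 most responsive voxels (grand-mean response — the
synthetic analogue of an orthogonal all-stimuli-versus-baseline localizer,
selected once, not per fold), voxel-wise mean subtraction across the full
(run × condition) matrix, then for each numerosity pair a linear SVM with
$C = 1$ trained on the five retained runs (collapsing item size and field
area, six patterns per class per run) and tested on the held-out run of
the 6-fold leave-one-run-out cycle. Pair accuracies are averaged,
unweighted, into the subject's mean accuracy; chance is 0.5.

Numerical conventions: decision values exactly at zero are counted as
errors for both classes (so the brute-force primal-hinge oracle used in
tests has an unambiguous target); no scaling beyond mean subtraction is
applied (`e1071::svm(..., scale = FALSE)`); a stricter fold-wise centering
variant (`fold_center = TRUE`) exists but is off by default, mirroring the
single whole-matrix centering of the original protocol.
`task_decoding()` applies the same machinery with the task as the class
label, collapsing all 18 conditions.

## 5. RSA multiple regression

`neural_rdm()` averages the run-wise betas to one pattern per condition
(the closest synthetic equivalent of re-estimating a single concatenated
GLM beta), restricts to the selected voxels, mean-centers voxel-wise
across conditions, and takes $1 - r$ correlation distances. `rsa_fit()`
then regresses the 153-pair neural vector on the z-scored predictor
vectors with intercept, in fixed row-major pair order; `rdm_vif()`
computes $VIF_k = 1/(1 - R_k^2)$ on the same z-scored vectors (never on
0–1 display-scaled matrices, which `scale_01()` provides separately).

**The z-scoring decision.** Whether the *neural* vector should be
standardised alongside the predictors is genuinely ambiguous in
descriptions of this analysis. The package default standardises the
predictors only, for a substantive reason discovered during validation:
dividing the neural vector by its own standard deviation couples all
betas through a shared normaliser, so a selective attentional
amplification of the number component *mathematically* deflates every
other dimension's beta when fits are compared across tasks — the analysis
would manufacture apparent task effects on non-numerical dimensions that
the generative model does not contain. With predictors-only z-scoring the
non-numerical betas are task-stable under a number-selective gain (the
acceptance harness verifies both this and the power of the number
contrast). The neural correlation-distance vector is already on a common
scale across subjects, so cross-subject aggregation remains valid.
`z_neural = TRUE` restores full standardisation, under which betas are
additionally invariant to affine rescaling of the neural RDM (asserted in
the test suite); betas are invariant to the predictor log base in either
mode, because z-scoring absorbs the scale factor.

Reduced models (`"orthogonal_only"`: $N$, $S$, $TFA$;
`"non_numerical_only"`: all but $N$) are fitted by predictor subset; the
full model's $R^2$ bounds both from above on any neural RDM.
Rank-deficient predictor sets fail with the collinear set named; exactly
duplicated predictors yield infinite VIFs with a warning rather than an
error, since VIF is a diagnostic.

## 6. Group statistics

`one_sample_t()` (accuracies vs the theoretical 50% chance),
`paired_t_with_d()` (task contrasts; Cohen's $d_z = \bar d / s_d$ by
default, the paired-design convention — a pooled-SD variant is exposed),
and `rm_anova()` — fully within-subject ANOVA with Greenhouse–Geisser
$\varepsilon$ (Huynh–Feldt optional), reporting $F$ at
$(\varepsilon\,df_1, \varepsilon\,df_2)$, with $\varepsilon = 1$ exact
for two-level factors. The heavy lifting is delegated to `car::Anova`'s
multivariate route; tests pin the behaviour to the $F = t^2$ identity,
null-rate calibration, and a directional check that the correction moves
type-I rates toward nominal under engineered sphericity violations.
Post-hoc contrasts are uncorrected by default (a Holm adjustment is a
one-liner with `p.adjust` on the returned p-values).
`linear_trend()` regresses per-ROI group means on ordinal position —
the "does numerosity information grow along the hierarchy" test.

## 7. Orchestration, determinism and problem sizes

`run_experiment()` composes the chain per ROI preset and subject and
persists every intermediate; reruns with the same config and seed are
identical (group tables serialise at 6 significant digits; per-subject
tables at full precision). `audit_design()` prints the grid, the
condition-level dimension correlations, the predictor-RDM correlation
matrix and the VIFs in one call.

Validation problem sizes were chosen to make the test suite a desk-scale
object: the recovery harness uses 50 replicates of 20-subject cohorts
(power and selectivity of the amplification signature), 200 replicates
for the null calibration of the number contrast, 100 replicates for
psychometric recovery at the full 432-trial design, and 100 label
permutations for the decoding null; brute-force decoding oracles run on
instances of at most six training points, where the primal hinge
objective can be minimised directly.

## 8. Known limitations

* The simulator's subjects share one voxel population; between-subject
  variance is noise-driven only, which makes group tests well calibrated
  but understates real between-subject heterogeneity.
* Voxel noise is i.i.d.; spatially correlated noise, which inflates RDM
  structure in real data, is not modelled.
* Voxel selection by grand mean is orthogonal to condition contrasts in
  the generative model by construction; with real localizer data the
  orthogonality is an experimental-design property, not a theorem.
* The psychometric fit estimates no lapse parameter by default; observers
  with non-negligible lapse rates bias $\sigma$ upward unless `lapse` is
  set.
* Printed collinearity diagnostics of the original design are reproduced
  only up to the unknown exact stimulus values (nominal reconstruction,
  deviations of a few percent; see Section 1).
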