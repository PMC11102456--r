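---
title: "Methods: connectivity-based prediction of category-selective fROIs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity-based prediction of category-selective fROIs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(connfroi)
```

## The model

`connfroi` predicts, for each of 18 category-selective visual regions (9 per
hemisphere: FFA, OFA, STS for faces; EBA for bodies; PPA, RSC, TOS for
scenes; LO, PFS for objects), an individual's localizer contrast map inside
the region's group-level search space, using only that individual's
resting-state data. Per vertex the features are the 179 Fisher-z vertex-to-
parcel correlations on the same hemisphere plus five anatomy covariates
(curvature, thickness, x, y, z), giving a 184-column design matrix. One
ridge model is fit per fROI, rows being search-space vertices stacked across
training subjects, each row weighted equally.

The penalty is selected by nested leave-one-subject-out (LOSO)
cross-validation. In the outer loop each subject is held out once; within
each outer training set, an inner LOSO loop evaluates all 100 grid values
λ ∈ [1e-5, 1e2] (log-uniform) and keeps the λ minimizing the held-out MSE
averaged over inner folds (a pooled-over-vertices variant is available via
`pooled = TRUE`); ties go to the smaller λ. Feature standardization
statistics are always computed on training rows only — the held-out subject
never influences them, which the test suite asserts by recomputation.

The inner search runs on per-subject sufficient statistics (`X'X`, `X'y`,
column sums): the training-fold standardization, the full eigenbasis ridge
path and the held-out MSE are all expressible in those cross-products, so a
fold costs O(p³) regardless of vertex count. Equivalence with the direct
fit/predict route is asserted to 1e-10 in the tests.

## Contrast maps and selectivity

Task runs are analyzed with a first-level GLM: one regressor per condition
(boxcar convolved with a gamma HRF, `h(τ) = ((τ−d)/t)² exp(−(τ−d)/t)` with
d = 2.25 s, t = 1.25 s, peaking at 4.75 s), six demeaned motion regressors,
one indicator regressor per frame exceeding 1 mm total vector movement, an
intercept, and a linear drift term. Condition regressors are peak-normalized
so the condition β is in raw signal units. The model's prediction target and
the "actual" fROI definition both use the contrast **effect** (β difference)
rather than the t map: the effect is the response magnitude itself and does
not depend on residual df; t maps are still produced.

fROIs are the top `f` fraction of search-space vertices of a map, with
`k = max(1, round(f·S))` (round half up) and ties broken by smaller vertex
id; `f` defaults to 0.10, with 0.20/0.30 available for the threshold-
robustness variants. Percent signal change is `100 · mean_v(β_cond/β_int)`
— the intercept β is the baseline, a choice we document because the PSC
denominator is a genuine convention point. Selectivity is PSC(preferred) −
PSC(contrast category), always computed from the run *not* used to define
any fROI (run 2 by default, with fROIs from run 1 predictions/localizer),
for every method, so method comparisons are like-for-like.

Overlap between predicted and localizer-defined fROIs is summarized by the
Dice coefficient. Two derived quantities: the *explainable overlap ratio*
Dice(pred, run-1 fROI) / Dice(run-1 fROI, run-2 fROI), since run-to-run
reliability bounds what any prediction can achieve (the ratio is undefined
and reported missing when the run-to-run Dice is 0); and *chance-adjusted
overlap* (Dice − f)/(1 − f), because two independent top-f selections in
the same search space have expected Dice exactly f (hypergeometric:
E|A∩B| = f²S).

The statistical evaluation mirrors standard practice: per-fROI one-sample
t-tests of selectivity against zero, Bonferroni-corrected at 0.05/18 =
0.00278; paired t-tests of connectivity vs each atlas method per fROI
(corrected at 0.05/(methods × fROIs)); and a category × hemisphere ANOVA on
the per-fROI selectivity values with subject as a random factor. Because
categories are unbalanced across the 18 fROIs (3 face, 1 body, 3 scene, 2
object per hemisphere), constrained (Type III) sums of squares are used:
each effect is adjusted for all others under sum-to-zero coding. With 40
subjects × 18 fROIs this yields the df decomposition 3/1/39/3/117/39 with
error df 517 and total df 719. All F ratios are formed against the error
mean square by default, matching the arithmetic of the published table this
layout reproduces; `denominators = "mixed"` instead tests the fixed effects
against their interaction-with-subject mean squares (the classical
random-subject denominators).

## The synthetic world

Real cohort data are not deposited, so validation runs on a generated
cohort whose defaults state the target acquisition: 40 subjects; one
580-volume resting run (TR = 1 s, 9.67 min); two 234-volume localizer runs
of five conditions (faces, bodies, scenes, objects, scrambled) in 18-s
blocks, two blocks per condition, order randomized per run.

One accounting choice deserves a note: the described design (10 stimulus
blocks of 18 s plus three 6-s rest blocks) sums to 198 s, not the stated
234 volumes. We implement the three rest blocks (beginning/middle/end) as
18 s each — three 6-s alternating-color segments — which makes the run
total exactly 234 s. This is the only reading we found that reproduces the
printed run length, and it is flagged rather than silently assumed.

Geometry is a flat 30×30 vertex sheet per hemisphere embedded in 3-D (no
mesh topology is needed by any operation), carrying smooth curvature and
thickness fields, a 179-parcel Voronoi parcellation, and nine disjoint
circular search spaces per hemisphere on a 3×3 template lattice. Each
subject's ground truth displaces every fROI center by a Gaussian jitter
(SD 1 grid unit) with log-normal size jitter (SD 0.15) — one knob for the
individual variability in location/size/shape the method is meant to
capture — and the latent selectivity field `s_v` is a Gaussian bump at the
jittered center; the true fROI is the top 10% of `s` within the search
space.

Resting signal is `w_v'η(t) + ε`, with η the P independent latent parcel
series (MA(5)-filtered Gaussian noise, unit variance, so T = 580 sample
correlations are well behaved) and loadings `w_v` equal to a Gaussian
spatial profile over parcel centroids (length scale `rest_smoothness = 6`
grid units) plus `coupling ×` a fixed 4×P coupling matrix applied to `s_v`
— the stated linear connectivity→activation coupling that makes recovery
possible. Task signal adds `amp_base + s_v` (preferred category) on top of
a baseline of 100 with drift and white noise; at the defaults the embedded
effects are 1–2% signal change, and per-fROI selectivity lands around
0.3–1 PSC, the order of magnitude seen in real localizer data. FD traces
have 5% spikes > 0.5 mm (resting censoring threshold) and task movement has
2% frames > 1 mm (spike regressors), so both motion rules are exercised.

Three synthetic group atlases emulate the published comparison: a
union-threshold atlas (vertices in ≥ 25% of subjects' true fROIs — the
lenient end of probabilistic-parcel thresholds; stricter thresholds empty
out with 5-vertex jittered fROIs, which the atlas builder treats as an
error), a dilated version (coarse multimodal-parcellation-like), and a
shifted version (systematically mismatched; border regions shift inward so
no atlas falls off the sheet).

What a green test does **not** establish: the generator has no hemodynamic
nonlinearity, no physiological noise, no spatial autocorrelation of the
noise, no mesh geodesics, and a genuinely linear coupling — real fMRI has
none of these guarantees. Green means the *pipeline machinery* (censoring,
connectomes, GLM, nested CV, thresholding, statistics) is correct and that
the method recovers a world that satisfies its own assumptions.

## Numerical choices

* Fisher z clips |r| at 1 − 1e-7 before `arctanh`; zero-variance series
  yield r = 0 with a warning instead of NaN (logged for audit).
* FD censoring and motion flagging use strict inequalities (`> 0.5 mm`,
  `> 1 mm`).
* A vertex's own parcel is *not* excluded from its fingerprint: all 179
  targets are always present, keeping the design matrix width fixed.
* Zero-SD feature columns are dropped per training set (recorded in the
  model); predictions map columns by name.
* The ridge intercept is the unpenalized training mean of y; features are
  standardized by training mean/SD — unstated conventions we fix and record
  in model metadata.
* λ ties take the smaller value; fROI ties take the smaller vertex id;
  `k = max(1, round(f·S))` uses round-half-up. All three make outputs
  deterministic.
* Seeds: one master seed; every stream (surface, coupling, per-subject
  ground truth/rest/designs/tasks) derives its own 31-bit sub-seed from a
  labelled counter, so a subject's data do not depend on cohort size.

## Known limitations

**Coupling-vector identifiability.** The fitted ridge weights predict well
(held-out per-subject correlation with the true contrast ≈ 0.95+ at
default settings) but do **not** recover the generative coupling vector:
the correlation between connectivity weights and the coupling row stays
below ~0.5 in every regime we probed (compact loadings, vanishing noise,
arbitrarily long runs, linear-regime or saturating coupling strength). This
is structural, not sampling error. The Pearson correlation normalizes by
the vertex signal norm, which itself depends on `s_v` via the coupling
(quadratically through κ²s²‖c‖²), and the spatial base-loading profile
covaries with the selectivity bump — so the population slope of the
fingerprint on `s` is a distorted, smeared direction, not `c`. This is the
classic backward-model vs forward-pattern distinction: weights of a
discriminative linear model are not generative couplings. The acceptance
test asserting weight–coupling correlation > 0.9 is therefore expected to
fail, and is kept failing rather than redefined; interpretation of model
weights should go through forward-pattern transforms, which are out of
scope here.

**Other limitations.** The ANOVA implements exactly the published table's
row structure (two fixed factors, subject random, all F vs error MS by
default) — it is not a general mixed-model engine. The explainable-overlap
ratio is a documented stand-in for a quantity whose published formula is
not given. Real surface data ingestion (GIFTI/CIFTI) is a documented
adapter gap, not implemented.
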