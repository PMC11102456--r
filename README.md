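# connfroi

Predicting category-selective visual regions from resting-state functional
connectivity.

## The problem

The ventral visual stream contains functional regions of interest (fROIs)
specialized for faces (FFA, OFA, STS), bodies (EBA), scenes (PPA, RSC, TOS)
and objects (LO, PFS). The gold standard for locating them in an individual
is a task-based localizer scan, but many datasets have resting-state fMRI
only. `connfroi` implements the alternative: predict each individual's fROIs
from their **resting-state connectivity fingerprint**.

For each of the 18 regions (9 per hemisphere) the model predicts, for every
vertex *v* in the region's group-level search space, its localizer contrast
response *y_v* (e.g. faces − objects) from the vertex's connectivity
fingerprint plus anatomy:

```
y_v  ≈  w' [ z_v1 … z_vP , curv_v , thick_v , x_v , y_v , z_v ]
z_vp =  arctanh( cor(x_v(t), m_p(t)) )          (Fisher z)
```

where `m_p` is the mean resting timeseries of parcel *p* among the P = 179
ipsilateral targets, and `w` solves a ridge (ℓ2-penalized) regression. The
penalty λ is chosen from 100 log-spaced values in [1e-5, 1e2] by **nested
leave-one-subject-out cross-validation**: an inner LOSO loop over the
training subjects picks the λ minimizing held-out MSE; the outer loop
applies the model to the left-out subject. The predicted fROI is the top 10%
of search-space vertices of the predicted map; selectivity is evaluated as
the percent-signal-change difference PSC(preferred) − PSC(contrast) on an
independent localizer run, and compared against localizer-defined and
atlas-defined regions with paired t-tests (Bonferroni 0.05/18) and a
category × hemisphere ANOVA with subject as a random factor (Type III SS).

Because no subject data are deposited, the package ships a **synthetic
cohort generator**: 40 subjects with one 580-volume resting run and two
234-volume localizer runs (five conditions in 18-s blocks), subject-specific
fROI locations, and a known linear coupling from connectivity loadings to
activation, so the whole pipeline can be validated against ground truth.

## Worked example

```r
library(connfroi)

## a small but complete synthetic world
cfg <- validate_config(list(
  cohort = list(n_subjects = 8, vertices_per_hemi = 300, seed = 11),
  seed = 11, log_level = "quiet"))
res <- run_pipeline(cfg)

res$comparison$summary
#>          method n_frois n_selective mean_selectivity
#> 1  connectivity      18          17        0.8690437
#> 2     localizer      18          14        0.6955154
#> 3   atlas_union      18          12        0.5019494
#> 4 atlas_dilated      18          17        0.3383714
#> 5 atlas_shifted      18           2        0.1320477
```

17 of 18 connectivity-predicted fROIs are significantly selective for their
preferred category at the Bonferroni threshold 0.05/18 = 0.00278 (the mean
selectivity of ~0.87 is in percent signal change), and the connectivity
fROIs are more selective on average than any synthetic group atlas —
the qualitative pattern the method is designed to show. Per-region detail
lives in `res$comparison$selectivity_tests`, per-subject overlap with the
localizer-defined fROIs in `res$overlap`, and the ANOVA in `res$anova`.

Single pieces are exported too:

```r
co   <- generate_cohort(cohort_config(n_subjects = 8, vertices_per_hemi = 300, seed = 11))
dat  <- froi_training_data(co, "rFFA", run = 1)   # per-subject (X, y)
cv   <- loso_predict(dat, lambda_grid())          # nested LOSO predictions
ssv  <- with(co$surface, vertex[!is.na(froi) & froi == "rFFA"])
froi <- define_froi(cv$predicted[["sub-01"]], ssv, f = 0.10, froi = "rFFA")
```

## Command line

```sh
Rscript -e 'connfroi::connfroi_cli()' simulate --seed 1 --out cohort/
Rscript -e 'connfroi::connfroi_cli()' run-all  --seed 1 --out results/
```

Stages (`connectome`, `glm`, `train`, `predict`, `define-froi`, `evaluate`)
can also be run one at a time against a simulated cohort directory; each
reads and writes plain TSV/JSON artifacts (see `connfroi_cli()` help).

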