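# radstab

**Segmentation-stability analysis of radiomic features in R.**

Radiomic features — histogram, shape and gray-level texture descriptors of
a lesion on CT or MRI — are computed over a segmentation mask, and every
feature inherits the variability of that delineation. `radstab` quantifies
this: it scores each feature's reliability across an ensemble of plausible
segmentation outlines, groups features into reliability signatures, and
measures how much a feature's (un)reliability costs when the features feed
a survival model. It is aimed at researchers designing radiomics analyses
who need a principled, fully reproducible way to pre-select features by
delineation robustness before modelling.

## The statistics at the core

**Reliability.** For each feature, the lesions × outlines matrix is scored
with the one-way random-effects intraclass correlation

```
ICC(1) = (MS_B − MS_W) / (MS_B + (k − 1)·MS_W)
```

where `MS_B` and `MS_W` are the between- and within-lesion mean squares of
the one-way ANOVA over `n` lesions and `k` outlines. Features are ranked
into quartiles and into threshold signatures: **high** (ICC > 0.99),
**low** (ICC < 0.75) and **all** (strict inequalities; boundary values are
excluded).

**Survival.** Cox proportional-hazards models (Breslow partial likelihood,
Newton iterations with step-halving, training-fold standardization) are
built per signature with sequential forward selection, starting from the
feature with the highest univariate Harrell concordance index
(C = P(risk ordering matches failure ordering); 0.5 random, 1.0 perfect).
Under five-fold cross-validation stratified on one-year survival intervals
× event status, each fold's fixed model is scored once per segmentation
(the reference outline plus each of the 100 variants), giving a C
distribution per signature whose mean and spread are compared with
Friedman, paired Wilcoxon signed-rank and Bartlett tests at
Bonferroni-adjusted α = 0.05/2, with D'Agostino–Pearson normality
pre-checks.

**Synthetic cohorts.** Because real multi-outline cohorts need expert
raters or a generative segmentation network, the package ships a
first-class phantom generator: textured elliptical lesions with irregular,
blurrable boundaries; outline ensembles drawn by thresholding the signed
distance transform at a correlated Gaussian displacement field (displacing
fuzzy boundary segments more than sharp ones); and exponential
proportional-hazards survival driven by the noiseless ground-truth
geometry. Everything is reproducible from one master seed.

## Worked example

```r
library(radstab)

cohort   <- makeCohort(nPatients = 40,
                       perturb = perturbationSpec(nVariants = 60),
                       masterSeed = 7)
prep     <- preprocessCohort(cohort)              # crop + exclusion rules
features <- extractFeatures(prep, featureConfig(wavelet = FALSE))

icc <- iccTable(features, "automatic")
head(icc[, c("feature_name", "icc", "quartile")], 3)
#>                          feature_name       icc quartile
#> 1         original.firstorder.Maximum 0.9977516       Q1
#> 2             original.firstorder.P90 0.9966101       Q1
#> 3 original.firstorder.RootMeanSquared 0.9959897       Q1

sig <- thresholdSignatures(icc)
lengths(sig)
#> high  low  all
#>    8    4   62

cv   <- stratifiedFolds(cohortSurvival(cohort), nFolds = 5, seed = 7)
high <- evaluateSignature(features, cohortSurvival(cohort), sig$high, cv, "high")
low  <- evaluateSignature(features, cohortSurvival(cohort), sig$low,  cv, "low")
all_ <- evaluateSignature(features, cohortSurvival(cohort), sig$all,  cv, "all")

high
#> C-index distribution [high]: 305 values, mean 0.6817, sd 0.1317
low
#> C-index distribution [low]: 305 values, mean 0.5209, sd 0.151

compareSignatures(high, all_, low)
#> Signature comparison (alpha_adjusted = 0.025 )
#>   mean C: high 0.6817, all 0.5951, low 0.5209
#>   SD C:   high 0.1317, all 0.1891, low 0.151
#>            comparison   statistic      p_value stars
#>        normality_high    36.40486 1.243899e-08   ***
#>         normality_all     2.27018 3.213932e-01    ns
#>         normality_low    10.26018 5.916038e-03    **
#>              friedman    82.62994 1.140611e-18   ***
#>  wilcoxon_high_vs_all 20077.50000 5.342351e-13   ***
#>  bartlett_high_vs_all    38.85617 4.562085e-10   ***
#>   wilcoxon_low_vs_all 15031.00000 1.559917e-03    **
#>   bartlett_low_vs_all    15.25439 9.395795e-05   ***
```

Reading the output: of 62 features, 8 survive outline perturbation almost
unchanged (ICC > 0.99) and 4 are outline-fragile (ICC < 0.75). The model
restricted to the reliable 8 discriminates survival clearly better
(mean C 0.68) than the model built from the fragile 4 (0.52, barely above
random), and the Wilcoxon/Bartlett rows confirm the location and spread
differences at the adjusted α. The 305 values are 5 folds × (1 reference +
60 variant) outlines; each distribution's within-fold spread is the part
attributable to segmentation alone (`high$sdWithinFold`).

The same analysis, end to end with artifacts on disk, is one call:

```r
res <- runPipeline(defaultConfig(), outDir = "run1", seed = 7)
makeReport("run1")   # figure-data tables: ICC quartiles, ICC by family, C by signature
```

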