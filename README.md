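# alscourse

Modelling the disease course of amyotrophic lateral sclerosis (ALS)
from longitudinal clinical trial records.

Pooled ALS trial databases record a revised functional rating scale
(ALSFRS-R, 12 items, total 0–48, lower = worse) together with scores of
laboratory and vital-sign variables at irregular visit days, and a
survival outcome that is right-censored for about half of the subjects.
`alscourse` implements a complete analysis chain for such data:

1. **Cleaning** of long-format visit records: drop records with missing
   time points or non-numeric/out-of-range values, average duplicated
   time points, merge synonymous variable headings, and back-calculate
   derivable instrument scores (no other imputation).
2. **Trajectory fitting.** Each subject's series is fitted to four
   decline models sharing the interpretation *A* = baseline value at
   day 0 and *k* = progression rate per day — linear `A − kt`,
   exponential `A·e^(−kt)`, harmonic `A/(1 + kt)` and Weibull
   `A·e^(−(kt)^b)` — by bounded simulated annealing on a Gaussian
   likelihood (equivalently, least squares), with *k* ∈ [−5, 5]/day,
   *b* ∈ [0.0001, 5], and *A* ≤ 53 for the ALSFRS-R total. A Weibull
   whose shape degenerates to its bounds or to 1 collapses to the
   exponential.
3. **Model selection.** Families are ranked per subject by
   small-sample-corrected AIC, `n·ln(SSE/n) + 2p + 2p(p+1)/(n−p−1)`,
   and by RMSE, with the equivalence rules |ΔAICc| < 2 and
   ΔRMSE < 10% of the top model. The exponential fit is used for all
   downstream features.
4. **Stratification.** Binary fast/slow progression classes from
   k-means/PAM clustering of the fitted ALSFRS-R rates, and binary
   high/low death-risk classes from k-means on days to death (last
   follow-up as a proxy when death is unrecorded), with the class
   threshold at the cluster-center midpoint.
5. **Survival.** Univariate Cox regression of survival on progression
   class (Efron ties) and Kaplan–Meier curves.
6. **Prediction.** Five experiments (decline class from trajectories or
   baseline, continuous ALSFRS-R *k* from baseline, survival class from
   trajectories+baseline or baseline) with RUSBoost, AdaBoost.M1,
   random forests, naive Bayes and decision trees under repeated
   stratified 60/40 holdout, permutation importance, and
   importance-ranked reduced-model search.

Because the real pooled databases are registration-restricted, the
package includes a **synthetic cohort generator**
(`simulate_cohort()`) that emulates their structure — irregular visits,
latent progression classes, correlated and censored death times,
missing cells — with full ground truth, so every stage is testable.
See the vignette `vignettes/disease-course-modelling.Rmd` for the
model details and design rationale.

## A worked example

```r
library(alscourse)

co <- simulate_cohort(cohort_config(n_subjects = 200, seed = 2))
an  <- als_pipeline(co, control = anneal_control(restarts = 2), seed = 1)
an
```

```
ALS disease-course analysis

Best-fit census (fraction of subjects):
       family criterion fraction
1 exponential      aicc    0.081
2    harmonic      aicc    0.448
3      linear      aicc    0.453
4     weibull      aicc    0.017
5 exponential      rmse    0.076
6    harmonic      rmse    0.233
7      linear      rmse    0.279
8     weibull      rmse    0.413

Decline classes (pam, 2 clusters):
  fast: 40 (21%), slow: 148 (79%)
  cluster centers (k/day): 0.000531, 0.00414
Survival classes (k-means, 2 clusters):
  high death risk: 158 (79%), low: 42 (21%)
  centers 191 / 521 days; threshold 356 days

Univariate Cox: fast vs slow progression
  HR = 2.81 (95% CI 1.63-4.84), p = 0.000199
  n = 148 slow / 40 fast, 86 events
```

The decline clustering recovers the planted 21% fast-progressor
structure (cluster centers 0.0005 vs 0.004 per day: fast subjects lose
ALSFRS-R points roughly eight times faster); the survival clustering
splits days-to-death at the cluster-center midpoint; the Cox model
shows the strong excess hazard of fast progressors. Two honest
features of the output are worth noting. The proxy use of last
follow-up for unrecorded deaths pulls censored subjects below the
threshold, so the derived high-risk share exceeds the latent one — a
bias the generator reproduces on purpose. And the best-fit census
concentrates on the exponential family only when decline is strong
relative to noise; for the slow-progressing majority the families are
nearly indistinguishable (see the vignette), which is why the pipeline
proceeds with the exponential fit for everyone regardless of the
census.

Prediction experiments then run on the fitted features:

```r
run_experiment(an, co, "decline_traj", n_repeats = 20, seed = 21)
```

```
Repeated holdout (20 repeats, n = 188, rusboost/classify)
  mean AUC = 0.96 (SD 0.0217)
  mean confusion (row %):
      predicted
actual slow fast
  slow 93.6  6.4
  fast 16.6 83.4
```

The same labels predicted from baseline values alone lose most of the
fast-class sensitivity — the central qualitative finding this design
reproduces.

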