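# accelcal

Calibration of wrist-worn accelerometer physical-activity cut points for
preschool-age children, against a hip-worn reference.

## The problem

Accelerometers summarise movement into per-epoch vector-magnitude (VM)
counts, `VM = sqrt(x² + y² + z²)`. Time in sedentary behaviour (SB), light
(LPA), moderate (MPA) and vigorous (VPA) physical activity is obtained by
comparing counts-per-minute (cpm) values with intensity *cut points*. For
preschoolers, validated cut points exist for the hip placement
(SB ≤ 820 cpm, LPA 821–3908, MPA 3909–6112, VPA ≥ 6113), but children
tolerate wrist-worn devices far better. `accelcal` implements the
simultaneous-wear calibration design: paired hip and wrist epoch counts are
collected, the hip cut points define reference labels, and wrist cut points
`(t₁, t₂, t₃)` — partitioning the integer cpm scale into
`[0,t₁] ∪ [t₁+1,t₂] ∪ [t₂+1,t₃] ∪ [t₃+1,∞)` — are derived by three
procedures:

* **ROC threshold search** — three cumulative dichotomies (SB vs above,
  SB+LPA vs above, below-VPA vs VPA), each threshold chosen to minimise
  |sensitivity − specificity| over the observed unique cpm values;
* **ordinal (cumulative-logit) regression** — a proportional-odds fit
  `logit P(Y ≤ k | x) = αₖ − βx`, epochs assigned to the
  argmax-probability class, cut points read off the assignment extrema;
* **univariate k-means (k = 4)** — unsupervised clustering of the wrist
  counts alone, solved *exactly* by dynamic programming (optimal 1-D
  clusters are contiguous), cluster maxima becoming the cut points.

Derived cut points are evaluated against the hip reference by per-class
sensitivity/specificity/FPR/FNR, Cohen kappa (per class via one-vs-rest
binarisation, plus multiclass overall), overall accuracy with and without
pooling MPA+VPA into MVPA, and daily minutes per intensity level.

Because the original study data are not public, the package includes a
first-class synthetic generator (Markov activity states with a prescribed
stationary occupancy, state-conditional lognormal counts, a monotone
hip→wrist linkage with multiplicative noise, injected non-wear blocks)
that reproduces the study conditions: 34 children × 3 five-hour days of
15-s epochs = 122,400 epochs.

## Worked example

```r
library(accelcal)

cfg <- pipeline_config(
  simulation = simulation_config(n_participants = 34, seed = 2026),
  seed = 2026)
bundle <- run_pipeline(cfg)
print(bundle)
```

```
<accel_bundle> 34 enrolled -> 34 analyzable -> 117108 matched epochs

Hip-reference class tally:
 class      n   pct
    SB  75093  64.1
   LPA  32178  27.5
   MPA   7089   6.1
   VPA   2748   2.3
  MVPA   9837   8.4
 Total 117108 100.0

Derived wrist cut points (cpm):
  roc     t1 = 2476, t2 = 10232, t3 = 16780
  olr     t1 = 2852, t2 = 12099, t3 = 22003
  kmeans  t1 = 3564, t2 = 11328, t3 = 25160
```

The tally is the hip-labelled class share of the 117,108 jointly worn
epochs (122,400 scheduled minus injected non-wear); it sits at the
generator's target occupancy of 64.2 / 28.0 / 5.5 / 2.3 %. Each method's
`(t1, t2, t3)` are wrist cpm upper bounds of SB, LPA and MPA; with the
default 3.2× hip→wrist linkage the mapped hip boundaries lie at
2624 / 12506 / 19558 cpm, and the three procedures land near them while
disagreeing with each other exactly as supervised-vs-unsupervised methods
do. Agreement of one method against the hip reference:

```r
print(bundle$agreement$kmeans)
```

```
<agreement_report> method: kmeans
  SB    sens  99.94  spec  89.69  fpr  10.31  fnr   0.06  kappa  0.92
  LPA   sens  82.23  spec  99.27  fpr   0.73  fnr  17.77  kappa  0.86
  MPA   sens  90.31  spec  97.93  fpr   2.07  fnr   9.69  kappa  0.80
  VPA   sens  67.72  spec  99.90  fpr   0.10  fnr  32.28  kappa  0.78
  MVPA  sens  94.12  spec  98.71  fpr   1.29  fnr   5.88  kappa  0.89

  overall (4-class): correct 93.73%, kappa 0.87
  overall (MVPA grouped): correct 94.58%, kappa 0.89
```

`write_report(bundle, "out", format = c("csv", "markdown"))` renders the
tally, calibration, agreement and daily-estimate tables to files. A thin
command-line wrapper lives at `inst/cli/accelcal.R`
(`Rscript inst/cli/accelcal.R run --out out --seed 1`).

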