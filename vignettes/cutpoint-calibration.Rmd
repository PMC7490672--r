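---
title: "Calibrating wrist-worn accelerometer cut points against a hip reference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating wrist-worn accelerometer cut points against a hip reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelcal)
```

## The problem

Triaxial accelerometers summarise movement into per-epoch *vector magnitude*
(VM) counts, the Euclidean norm of the three axis counts. Counts are turned
into time spent in sedentary behaviour (SB), light (LPA), moderate (MPA) and
vigorous (VPA) physical activity by comparing counts-per-minute (cpm) values
against *cut points*. Validated preschool cut points exist for hip-worn
devices (SB ≤ 820 cpm, LPA 821–3908, MPA 3909–6112, VPA ≥ 6113), but young
children comply far better with wrist-worn devices, for which few cut points
exist. `accelcal` implements the calibration design that addresses this:
children wear both devices simultaneously, the hip labels serve as the
reference, and wrist cut points are derived so that wrist-only classification
reproduces the hip labelling as closely as possible.

One detail of the hip reference deserves a note: the published intervals
leave the single value 6113 cpm unassigned (MPA ends at 6112, VPA is
"greater than 6113"). `accelcal` takes VPA as ≥ 6113 so the four intervals
tile the non-negative integers with no gap — classification must be a total
function.

## The synthetic study generator

The original calibration data are not public, so the package ships a
generator that emulates the study conditions and makes every downstream
stage testable: 34 preschoolers, 3 consecutive 5-hour preschool days,
15-second epochs (1200 epochs/day, 3600 per child, 122,400 in total).

The generator has three layers:

**Latent states.** The child's intensity state follows a first-order Markov
chain at epoch resolution. We use the "sticky" family
$P = s I + (1 - s)\,\mathbf{1}\pi^{\top}$, whose stationary distribution is
exactly the target occupancy $\pi$ for any stickiness $s \in [0, 1)$. The
default $\pi = (0.642, 0.280, 0.055, 0.023)$ is the observed preschool-day
class share; $s = 0.85$ gives mean bout lengths of roughly one to two
minutes, the sporadic short-burst pattern typical of this age group.

**Hip counts.** Given the state, hip counts per 15-s epoch are drawn from a
discretised lognormal (SB additionally has a 0.30 point mass at zero —
motionless epochs; VPA is shifted above the vigorous floor of 1529 counts).
The defaults (SB: meanlog log 55, sdlog 0.65; LPA: log 450, 0.38; MPA:
log 1225, 0.11; VPA: 1529 + lognormal(log 700, 0.60)) were set once so that
two stated calibration properties hold: (i) classifying the generated hip
counts with the hip cut points reproduces the latent state for ≈ 97–98 % of
epochs (ordinal separation with realistic overlap), and (ii) the *labelled*
class shares still match the target occupancy to better than one percentage
point — the upper-tail mass of each class that crosses a boundary is
approximately balanced by the mass crossing back.

**Wrist linkage.** Wrist counts are
$w = \mathrm{round}(g(h) \cdot \varepsilon)$ with $g(x) = 3.2x$ by default —
the approximate wrist/hip scale implied by published preschool cut points —
and $\varepsilon$ a multiplicative lognormal noise factor with unit median
and dispersion (sdlog) 0.20, a ≈ 20 % coefficient of variation chosen once
as a realistic between-placement variability. Any strictly increasing $g$
can be supplied. With dispersion 0 the linkage is deterministic and
monotone, the regime used for exact-recovery validation.

Non-wear is modelled as at most one block per day (default probability 0.1,
duration uniform on 90–180 min, affecting both placements — the child takes
the devices off). Blocks start on whole-minute boundaries: the detector
operates on the 60-s grid, and device removal mid-minute would make exact
mask recovery impossible by construction rather than by any property of the
detector.

All randomness flows from one master seed through named sub-streams
(`substream_seed()`), so any stage can be re-run independently and the whole
study is byte-reproducible.

### The well-separated validation emission

`well_separated_emission()` is an idealised regime, not a realistic one: the
state supports are disjoint intervals (SB 0–150, LPA 450–850, MPA 1100–1400,
VPA 1850–3300 counts/15 s) whose gaps are wide enough that the midpoint
between adjacent class centroids falls inside the gap. That condition
matters because an optimal one-dimensional k-means partition places its
cluster boundaries at centroid midpoints; when the midpoints sit in the
support gaps, the optimal clustering separates the states exactly, and all
three calibration procedures should recover the mapped reference partition
on every observed epoch. Passing that check validates the machinery, not
the realism of the data.

## Preprocessing

* **Vector magnitude** is rounded half-up to an integer, matching integer
  device exports; the rounding rule is stated so it is testable.
* **Re-integration** collapses epochs by summation (counts are conserved
  over complete windows; a trailing partial window is dropped with a
  warning). The analysis default is the 15-s grid with cpm = count × 4 —
  the only grid on which a 5-hour day yields the study's epoch totals — with
  60-s re-integration available as a config switch.
* **Non-wear detection** follows the standard zero-run rule: ≥ 90 min of
  consecutive zero-count minutes, tolerating ≤ 2-min non-zero interruptions
  only when flanked by ≥ 30 min of zeros on both sides. The parameters are
  the canonical published ones; detection runs on a 60-s grid derived from
  the data and the mask is expanded back to the analysis grid.
* **Alignment** intersects the two wear masks on the epoch index within a
  day (simulator output and device exports are both regular grids, so
  wall-clock matching adds nothing).
* **Exclusion**: participants whose matched data are missing on three or
  more consecutive scheduled days are excluded. The source rule ("more than
  3 consecutive days") is vacuous in a 3-day protocol; we read it as "3 or
  more" so that a participant with no valid day is excluded and anyone with
  a single valid day is retained, and log every decision.

## The three calibration procedures

All three consume the matched table of wrist cpm values with hip-reference
labels (the two supervised ones) or wrist cpm values alone (k-means).

**ROC threshold search.** Three cumulative dichotomies — SB vs above,
SB+LPA vs above, below-VPA vs VPA — are each scanned over the observed
unique wrist cpm values with "positive" meaning *above* the threshold. The
selected threshold minimises |sensitivity − specificity|; ties break toward
the smallest threshold so the result is deterministic and favours detection
of the higher class. Scanning only observed values is exact, not an
approximation: both error rates are piecewise constant between observed
values. Because the dichotomies are independent fits, the three thresholds
can cross on pathological labellings; that is reported as an error rather
than silently reordered.

**Ordinal (cumulative-logit) regression.** A proportional-odds model
$\mathrm{logit}\,P(Y \le k \mid x) = \alpha_k - \beta x$ is fitted by
maximum likelihood (BFGS with analytic gradients on a scaled predictor; a
ridge penalty of $10^{-6}$ on the slope keeps the optimum finite under
quasi-separable data, which noise-free linkages produce). Each epoch is
assigned the class with the highest predicted probability; with $\beta > 0$
the argmax class is non-decreasing in cpm, so predicted classes form
contiguous intervals and the cut points can be read off the assignment
extrema: SB bound = max cpm assigned SB, MPA and VPA bounds = min cpm
assigned to those classes (minus one on the integer grid), LPA spanning
between. A class that receives no argmax assignment is an explicit error —
with heavily sedentary-skewed training data the moderate class can collapse,
and silently emitting an empty interval would corrupt everything downstream.

**Univariate k-means (k = 4).** The number of clusters is fixed a priori by
the four intensity states. The default solver is an exact dynamic programme
over the sorted unique values (optimal 1-D clusters are contiguous), made
$O(k\,n \log n)$ by the monotone-argmin divide-and-conquer; it is
deterministic, provably optimal and needs no seed. The classic Lloyd
iteration (10 restarts, seeded) is available for comparison and can only do
worse in within-cluster sum of squares — a property the tests assert.
Cluster boundaries are reported as the maximum observed value of each lower
cluster, so when the optimal boundary falls in a gap between observed
values the reported bound is the largest observed member, matching the
max-within-category convention.

## Agreement and daily estimates

Per class, the package reports one-vs-rest sensitivity, specificity, FPR
(= 100 − specificity) and FNR (= 100 − sensitivity), plus a per-class Cohen
kappa computed on the one-vs-rest binarised labelings — the only
construction that yields one kappa per intensity level. Overall accuracy and
multiclass kappa are reported for the 4-class scale and again with MPA and
VPA pooled into MVPA; pooling can only move error cells onto the diagonal,
so grouped accuracy never falls below the 4-class value. Undefined ratios
(0/0) are reported as explicit undefined markers.

Daily estimates are minutes per class per participant-day
(epochs × epoch length), summarised as mean (SD) across participant-days
and as a percentage of *wear* time — the wear-based denominator is the only
one consistent with published percentage columns of this design, which do
not equal mean minutes divided by the scheduled 300 min. Method contrasts
use a paired percentile bootstrap of the mean daily difference (2,000
seeded resamples); the source design's analysis of covariance names no
covariate, so it is deliberately not reproduced.

## Numerical choices and degenerate inputs

* All percentages and integerisations round half away from zero
  (`round_half_up()`); base R's round-half-to-even would disagree with
  printed tables in boundary cases.
* Cut points live on the integer cpm grid; 15-s counts are compared after
  ×4 conversion. Adjacent published bounds differ by exactly 1 cpm, which
  forces integer semantics.
* The ROC tie-break (smallest threshold), the DP's deterministic optimum,
  and the ridge-stabilised ordinal fit make all three calibrations
  permutation-invariant in the epochs (the ordinal fit up to 1e-8).
* Degenerate inputs fail loudly: constant wrist counts, a missing intensity
  class in supervised training, fewer distinct values than clusters,
  crossing ROC thresholds, empty predicted OLR classes, mismatched epoch
  grids, unknown labels in ingested files.

## What the tests do and do not show

The validation suite checks, at fixed seeds: exact-solver equivalence
against brute-force oracles (DP vs exhaustive partitions at n ≤ 12, ROC vs
full scans, kappa vs the formula); exact recovery of the mapped reference
partition under the noise-free well-separated regime (50,000 epochs; the
ordinal method ≥ 99 %); ≥ 90 % agreement under the realistic default noise;
exact non-wear mask recovery on 100 simulated days with injected 90–180-min
blocks and zero false alarms at 89 min; and simulated hip-labelled class
shares within ±1.5 percentage points of the target occupancy at 122,400
epochs. The full pipeline runs at study scale (34 × 3 × 1200 epochs) in a
few seconds.

Passing these checks shows the machinery is correct under the generator's
assumptions: a monotone hip–wrist linkage with multiplicative noise,
state-conditional unimodal count distributions, and block-structured
non-wear. Real preschool data violate several of these — device-specific
filtering, posture effects that break monotonicity at the epoch level,
fragmented non-wear, day-of-week structure — so recovery rates here are not
predictions of field agreement; the published field agreement for this
design is substantially lower than the synthetic rates.

## Known limitations

* The raw 30 Hz acceleration → count conversion is proprietary and out of
  scope; the pipeline starts at epoch counts.
* The wrist external reference ships only its MVPA floor (16716 cpm); its
  SB/LPA boundary must be supplied by the user from the original source, and
  the comparison column is skipped with a notice otherwise.
* Per-class kappa as binarised kappa is a modelling choice; other
  per-class decompositions of multiclass kappa exist.
* k-means calibration is pooled across participants by default; a
  per-participant mode would need a pooling rule for the resulting
  per-child boundaries and is not implemented.
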