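---
title: "Morphodynamic screening and miscarriage-risk prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphodynamic screening and miscarriage-risk prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryoscreen)
```

## The problem

Among IVF embryos that implant successfully (a gestational sac on week 5),
roughly one in five is lost to first-trimester miscarriage (MC); the rest
proceed to live birth (LB). Both outcomes look alike under the standard
morphokinetic criteria used to select embryos for transfer, so the question
is whether subtler, quantitative morphodynamic structure in the time-lapse
recording — pronucleus (PN) motion, nucleolus precursor body (NPB)
arrangement, deviations from the typical cleavage-timing profile — carries
predictive signal. `embryoscreen` implements that analysis end to end:
a 314-feature catalog, a statistical-distance screening cascade, Monte-Carlo
cross-validated tree ensembles, and SHAP-based explanation. Because clinical
time-lapse data are private, the package ships a synthetic cohort and
zygote-movie generator with ground truth, and every stage is tested against
it.

## The feature catalog

The catalog is fixed at 314 named features in three blocks (the full list,
with definitions, is in
`system.file("extdata", "feature_dictionary.csv", package = "embryoscreen")`).

**Morphology (35).** Blastomere-size symmetry and fragmentation percentage
at the 2- and 4-cell stages (4), PN size (7) and location (3) features, NPB
count distributions (4), NPB spatial distributions within and between the
PNs (11), the annotated first-cleavage-plane angle (1), and ooplasm / zona
pellucida radii (5). Two members have short names used throughout:
\(f_1 = (\max_{i,j} d_{i,j})/R_{PN}\), the maximal pairwise NPB distance in
the small PN normalised by its radius, and \(f_2\), the ooplasm radius.
All are measured at a reference frame about an hour before PN fading
(tPNf). The published description pins only the per-group counts and the
\(f_1, f_2\) formulas; the remaining member definitions are this package's
choice, frozen in the data dictionary so the 314 total is testable. Where a
group is ambiguous (e.g. whether inter-PN NPB distances appear raw or
normalised), the dictionary records the choice rather than leaving it
implicit. A single NPB yields a maximal pairwise distance of 0 (an empty
pair set); zero NPBs yield a missing value, flagged — compactness you
measured and compactness you could not measure are different data.

**Morphokinetics (117).** The nine annotated event times (tPNa, tPNf,
t2..t8, hours post-ICSI), all 36 pairwise intervals and 36 pairwise ratios
in chronological catalog order (so intervals are non-negative whenever the
ordering invariant holds), and 36 distance-from-linear-regression (DLR)
statistics. For each event pair, an ordinary least-squares line is fitted
to the LB embryos only; an embryo's DLR is its unsigned perpendicular
distance from that line,
\(|s\,t_i - t_j + c|/\sqrt{s^2+1}\). It measures deviation from the average
timing profile of positively implanted embryos; \(f_3 = \mathrm{DLR}_{2,3}\)
and \(f_4 = \mathrm{DLR}_{5,6}\). DLR is reported unsigned, matching its
definition as a shortest distance; a signed variant exists behind an
argument but is excluded from the catalog.

**PN dynamics (162).** Forward (tPNa to tPNf) and reverse episodes of
Lucas-Kanade optical-flow tracking give per-frame PN positions in the
embryo frame of reference. The block comprises step-size and velocity
statistics (72), inter-PN distance statistics (18), and PN-to-embryo-centre
distance statistics, raw and normalised by the ooplasm radius (72). Eight
base statistics (min, max, mean, median, sd, first, last, sum) are used per
series, plus explicit large-vs-small contrasts: the max-step and
max-velocity ratios and the min-step and min-velocity differences per
direction. The published counts alone cannot say whether the selected
features \(f_5\) (max step of the large PN over max step of the small PN)
and \(f_6\) (\(|l_l - l_s|\), the absolute difference of the two
PN-to-centre distances at tPNf) are members of the 72-feature groups or
derived afterwards; this package makes them genuine catalog members, which
is why the contrasts replace a ninth base statistic in those two groups.
Forward and reverse episodes are kept as separate catalog axes rather than
merged, since both are computed but no merging rule is published.

## Optical-flow tracking

Fifteen mutually non-adjacent pixels (minimum spacing 2 px) are selected
inside the seed PN disc and tracked frame to frame with iterative
Lucas-Kanade flow over a 15 x 15 px neighbourhood; the PN position per
frame is the mean of the surviving tracks. Two implementation choices
matter:

* *Pixel selection is restricted to textured locations.* The flow equations
  are singular where the image gradient vanishes, and the interior of a
  rendered PN disc is flat: a uniformly random sample places most points
  where motion is unobservable and the tracked mean lags the true motion.
  Selection therefore samples randomly (seeded) among pixels whose local
  gradient energy is in the upper half of the disc — the standard
  "good features to track" consideration, applied with the lightest
  possible touch.
* *The trajectory is anchored at the annotated seed centre.* The mean of
  the sampled pixels is offset from the disc centre by a constant (about a
  pixel); since the seed centre is known at the start frame, the whole
  trajectory is shifted so frame 1 coincides with it. Displacements, which
  drive all step/velocity features, are unaffected.

Tracks are dropped when the flow system is ill-conditioned, the update
diverges beyond the half-window, or the point leaves the frame; fewer than
8 of 15 survivors marks the trajectory unreliable. Positions are reported
relative to the per-frame ooplasm centre (supplied, or estimated as the
centroid of the clearly-darker-than-background mask, which is unbiased for
the concentric rendered geometry). Single-level flow suffices because
per-frame motion in the simulated regime (≤ ~2 px/frame) is well inside
the 15 x 15 window; that is a documented validity limit, not a tracker
parameter.

Trajectories are classified as *stationary* when the end-to-end
displacement is below \(\theta_s R_{PN}\), else *linear* when straightness
(end-to-end over path length) is at least \(\theta_l\), else *curved*.
The taxonomy criteria are published but the thresholds are not;
the defaults \(\theta_s = 0.5\), \(\theta_l = 0.8\) are package choices and
both are configurable. On the synthetic suite the tracker's worst error is
well under the quarter-PN-radius fidelity bound used for quality control.

## The screening cascade

1. **Statistical distances.** Per feature, the two-sample KS p-value and a
   KL divergence estimate between the MC and LB value distributions.
   The KL estimator is unspecified in the source material; here it is a
   shared 20-bin equal-width histogram over the pooled range with a Laplace
   pseudocount, direction KL(MC‖LB), in nats. On \(10^5\) draws of
   \(N(0,1)\) vs \(N(1,1)\) it recovers the closed form 0.5 within 0.05.
2. **Threshold grid.** Six KS thresholds spaced +0.05 and three KL
   thresholds spaced −0.1 define 18 subsets of features with
   `ks_p < λ_i` and `kl > λ_j`. The base values are configuration, not
   published numbers; the defaults (0.01, 0.25) were fixed once so that
   roughly 5–30% of features qualify on the default synthetic cohort, the
   calibration rule the design prescribes. Subsets grow monotonically as
   thresholds loosen, by construction.
3. **Subset scoring.** Each non-empty subset is scored by stratified 90/10
   Monte-Carlo cross-validation (100 folds at study scale), training a
   random forest and a gradient-boosted model per fold and averaging
   validation AUCs. Stratification protects the 96/368 imbalance; a
   validation draw that loses a class is redrawn and logged.
4. **Ranking and redundancy.** The ten subsets with the highest combined
   RF+GB AUC (ties toward smaller subsets) are pooled; their union is
   ranked by each family's native importance averaged over all relevant
   folds, rank-averaged across families; the top eight get a pairwise
   Pearson matrix to expose redundancy.
5. **Backward elimination** removes, at each step, the feature whose
   removal costs least in combined AUC, producing the full series down to
   one feature; the working subset is the last one before a removal hurts
   *both* models.
6. **Two-step forward selection** then tests every pair from the top-ranked
   remainder added jointly; the best pair's lower-catalog-index member is
   retained (the published tie-break), for up to three cycles, stopping
   when no pair improves both models. Note an interaction worth knowing:
   because only the lower-index member of the winning pair is kept, a
   high-index informative feature can be passed over in a cycle — that is
   the selection rule as specified, not an accident.

**Leakage control.** The held-out test partition (balanced MC/LB) is
constructed first and never touched by screening: permuting its labels
changes no screening or training artifact, which is asserted by a test.
Within cross-validation, median imputation is fitted on each fold's
training split, and DLR regression lines are re-fitted on each fold's
training LB embryos when event profiles are supplied. The original
analysis fits DLR lines once on all LB embryos; that global behaviour is
available by simply not passing profiles, but fold-wise refitting is the
defensible default and the one used here.

## Prediction, evaluation, explanation

Model defaults are the study settings: gradient boosting with 6 trees of
depth 1 at learning rate 0.25; random forest with 65 trees of depth 3 and
Gini splits. "Averaging the cross-validated model's weights" is
operationalised as averaging the 100 fold-models' predicted MC
probabilities — averaging tree parameters is ill-defined — and the
integrated classifier averages the RF and GB ensemble scores.
Hyperparameter search samples uniformly from the published ranges and
scores by mean CV validation AUC (any optimizer over those ranges
satisfies the contract; random search is used). The RF range names
minimum-leaf and minimum-split sizes, mapped to ranger's `min.bucket` and
`min.node.size`.

AUC is computed by the rank (Mann-Whitney) statistic with ties counted
half, and equals brute-force concordant-pair counting (tested). Operating
points are chosen on the precision-sensitivity curve: a high-threshold
precision-favouring classifier and a low-threshold sensitivity-favouring
one; the defaults pick the highest threshold reaching sensitivity 0.25 and
the lowest reaching 0.75, and both are arguments — the published analysis
marks its thresholds only graphically.

Explanation uses exact additive tree attributions (TreeSHAP) from the
gradient-boosted ensemble — the family the published SHAP analysis
targets — averaged across folds on the log-odds scale, so base value plus
attributions reconstructs the fold-averaged margin exactly. Importance is
summarised by aSHAP: the mean absolute attribution signed +1 for correctly
classified embryos and −1 for misclassified ones (classification at
ensemble score 0.5, configurable), scoring impact on *accurate*
prediction. The precise aSHAP weighting in its original description is not
printed; the implemented formula is documented here and isolated in one
function.

## The synthetic cohort generator

The generator's defaults are the study conditions: 96 MC / 368 LB embryos,
PN visibility drawn from \(N(17, 2.5^2)\) hours. Event times are built
from positive increments (so chronology holds by construction) with
configurable pairwise linear relations; the default ties t3 to t2 and t6
to t5 with Gaussian residuals, reproducing the strong t2–t3 linear
correlation (empirical \(R^2 \approx 0.85\) on the default cohort).
Geometry (ooplasm/zona radii, PN discs, NPB positions) is drawn from
plausible pixel-scale distributions; PN trajectories are drifting random
walks over the visibility window, with the reverse episode the time
reversal of the forward one. Class effects are planted *after* feature
derivation as a mean shift of d pooled standard deviations on the MC rows
of named feature columns — the simplest structure under which screening
recovery is provable — and all other features are identically distributed
in both classes. Missingness is completely at random per cell (default
3%), with optional truncation of t5..t8 for a configurable day-3-transfer
fraction (default 0). No distributional description of the real features
is published, so these are explicitly free knobs emulating structure, not
estimates of the clinical data.

What passing tests on this cohort do **not** show: that the cascade
recovers the published six features on clinical data (those data are
private), that real PN dynamics resemble drifting random walks, or that
the planted-effect sizes match clinical effect sizes. What they do show:
the machinery — catalog bookkeeping, distances, grid, CV, wrappers,
ensembles, attributions — does what it claims under known ground truth,
with the class imbalance and missingness of the study.

Rendered movies emulate a zygote, not microscopy: flat-intensity discs
(background 0.78, zona ring 0.68, ooplasm 0.45, PN 0.62, NPB 0.18 on a
[0,1] gray scale) with logistic edge smoothing (σ ≈ 0.8 px), NPBs placed
by non-overlap rejection sampling and moving rigidly with their PN, plus
additive Gaussian noise. Trajectory taxa are exact parametric paths
(orbits, opposite-sense parallel lines, rest), so ground truth is exact by
construction. This is deliberately just enough texture for Lucas-Kanade.

## Numerical choices and degenerate inputs

* Event catalog order is fixed as (tPNa, tPNf, t2..t8) for all pair
  enumeration; ties in forward selection resolve to the lowest catalog
  indices; ranking ties resolve by catalog order.
* A zero earlier event time makes a ratio missing (flagged); a
  zero-variance predictor makes a DLR pair degenerate (flagged, no line);
  pairs with fewer than two complete LB cases yield no line.
* An all-constant feature reports KS p = 1 and KL = 0; features with fewer
  than two values in a class are skipped and flagged.
* Constant labels are rejected before fitting; single-class evaluation
  partitions raise an explicit error rather than returning a vacuous AUC.
* All randomness flows from explicit integer seeds through one generator;
  cohort generation is byte-identical under a fixed seed.

## Problem sizes used in the shipped analyses

The package-level checks run at desk scale, chosen once: subset scoring
with 15–25 Monte-Carlo folds and wrapper stages with 8–10 folds (fold
count is a precision knob — fewer folds give noisier AUC estimates, i.e.
a harder, not easier, recovery problem), a 20-movie tracking suite at 40
frames, and 20-seed screening-recovery experiments at the 96/368 study
composition. The `analysis/` drivers and `scripts/acceptance.R` state
their sizes inline; the 100-fold study-scale scheme is the default of
every fitting function.

## Known limitations

* Real-image segmentation and morphokinetic annotation are out of scope;
  annotations are inputs (in the study they were produced by
  embryologists and semi-automated tools).
* The first-cleavage-plane angle is consumed as an annotated scalar; no
  algorithm for it is published.
* TreeSHAP attributions are provided for the gradient-boosted family
  only; no installed tree-SHAP implementation exists for the RF backend,
  and the published SHAP analysis targets the boosted classifier.
* The clinical headline numbers (test AUC ≈ 0.68–0.69) are properties of
  a private multi-centre cohort and are not reproduction targets for the
  synthetic pipeline; the published earliest-prediction-time statement
  ties readiness to t6 via \(f_6\) although \(f_6\) is evaluated at tPNf
  (and \(f_4\) requires t6) — readiness here is computed as the maximum
  event-time requirement across the active subset, leaving the apparent
  inconsistency unresolved rather than silently fixed.
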