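---
title: "Validating automated smile-event classification against a human rater panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating automated smile-event classification against a human rater panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smileval)
```

## The problem

Facial expression recognition (FER) systems derive, from a tracked 3D face
mesh, a vector of *blendshapes*: normalized activations in $[0,1]$ for named
facial expression components (0 = neutral, 1 = fully expressed). Smiling is
carried by two bilateral action units — AU12, the lip corner puller
(`mouthSmile_L`/`mouthSmile_R`), and AU6, the cheek raiser
(`cheekSquint_L`/`cheekSquint_R`). Given short video segments (5 s at
10 frames/s, hence 50 frames) annotated by a panel of human raters as
containing a smile event or not, the question is whether a very simple
machine rule — *either side of the face exceeds a threshold* — can
reproduce the human consensus, and how to quantify that agreement.

`smileval` implements the full validation pipeline: segment-level feature
extraction, multi-rater consensus with Fleiss' $\kappa$, participant- and
class-stratified train/test splitting, fixed-grid ROC analysis with
Youden-optimal threshold selection, and test-half evaluation with
sensitivity, specificity and Cohen's $\kappa$. A seeded synthetic-data
generator emulates the statistical structure of such a study so every stage
is testable without access to any recordings.

## The classifier

A segment is reduced to one feature per blendshape: the **maximum** of its
frame series. A smile event is present if the expression appears at *any*
moment of the clip, and the maximum is the only aggregate for which
"some frame exceeded the threshold" and "the aggregate exceeded the
threshold" coincide. (The alternative aggregates — mean, sustained
exceedance — would conflate intensity with duration; the max decision is
flagged for sensitivity analysis in applications.)

The bilateral classifier for a pair $(L, R)$ with threshold $\theta$
declares a smile when

$$ (x_L > \theta) \;\lor\; (x_R > \theta) \iff \max(x_L, x_R) > \theta, $$

which is why `score_segments()` returns $\max(x_L, x_R)$ and a single ROC
sweep over that scalar score is equivalent to sweeping the OR rule.
"Exceeds" is read **strictly**: a score exactly equal to $\theta$
classifies negative. This matters only when a score coincides with a grid
threshold, and is documented because it shifts those ROC points by one
grid step.

## Threshold selection

The ROC is computed on a fixed grid $\theta \in \{0, 0.001, \dots, 1\}$
(1001 points, both endpoints included). At each $\theta$,
$\mathrm{TPR}(\theta)$ is the share of positive segments with score
$> \theta$ and $\mathrm{FPR}(\theta)$ the same share among negatives. The
operating threshold maximizes Youden's $J = \mathrm{TPR} - \mathrm{FPR}$;
among tied maximizers the **smallest** threshold is taken, which maximizes
sensitivity at equal $J$ and makes the choice deterministic.

The AUC is computed by trapezoidal integration over the unique
$(\mathrm{FPR}, \mathrm{TPR})$ points sorted by FPR then TPR, anchored at
$(0,0)$ and $(1,1)$. When no two scores fall inside the same 0.001 grid
cell and no score sits exactly on a grid point, every pair of segments is
resolved by some grid threshold and the trapezoidal AUC equals the
Mann–Whitney pairwise-concordance estimator exactly; the test suite checks
this identity on hundreds of random instances. Scores closer together than
the grid step are indistinguishable to the grid and count as ties — an
intrinsic property of a fixed-resolution sweep, not a defect of the
integration.

## Stratified splitting

The 50/50 split balances both participants and classes: within each
(participant × label) stratum the segments are shuffled by the seeded
generator and paired off alternately between the halves. Pure alternation
starting at "train" would push every odd stratum's surplus into the
training half, so the single leftover of each odd-sized stratum is pooled,
the pool shuffled, and its members alternated between the halves. Each
stratum is then imbalanced by at most one segment, and because the number
of odd strata has the parity of the total, an even total (e.g. 158
segments) always splits exactly 79/79.

## Agreement statistics

**Fleiss' $\kappa$** audits the rater panel. With $n_{ij}$ raters placing
item $i$ in category $j$, per-item agreement is
$P_i = (\sum_j n_{ij}^2 - r) / (r(r-1))$, $\bar P$ its mean,
$\bar P_e = \sum_j p_j^2$ the chance agreement from the overall category
shares, and $\kappa_F = (\bar P - \bar P_e)/(1 - \bar P_e)$. The standard
error is the Fleiss–Nee–Landis large-sample SE of overall kappa, which for
binary ratings reduces to $\sqrt{2 / (n\,r(r-1))}$; the package uses it
both for the Wald interval and for a one-sided $z$-test of $\kappa = 0$.
If every rating falls in one category, $\bar P_e = 1$ and the statistic is
signalled as undefined rather than returned as a number.

**Cohen's $\kappa$** quantifies machine–human agreement on the test half.
From the 2×2 confusion matrix, $p_o = (TP+TN)/n$,
$p_e = [(TP\!+\!FP)(TP\!+\!FN) + (FN\!+\!TN)(FP\!+\!TN)]/n^2$ and
$\kappa_C = (p_o - p_e)/(1 - p_e)$. The 95% interval is
$\kappa_C \pm 1.96\,\mathrm{SE}$ with

$$ \mathrm{SE} = \sqrt{\frac{p_o (1 - p_o)}{n (1 - p_e)^2}}, $$

and the $p$-value is a one-sided $z$-test against $\kappa = 0$ with null
standard error $\sqrt{p_e / (n(1-p_e))}$. Two conventions are deliberate:
the Wald interval is **not truncated at 1** (near-perfect agreement on
moderate $n$ legitimately yields an upper bound above 1, and truncating
would hide how wide the interval is), and the one-sided test is reported
because the scientific question is directional; at the agreement levels
involved the sidedness is immaterial.

```{r printed-cm}
cm <- confusion_matrix(tp = 27, fp = 2, fn = 1, tn = 49)
sens_spec(cm)
cohen_kappa(cm)
```

## The synthetic-data generator

No recordings ship with the package, so `simulate_segments()` generates
datasets with the statistical structure of a smile-annotation study.
Defaults define the study conditions and are chosen once:

* **158 segments of 50 frames** (5 s × 10 fps) over **9 participants**,
  assigned round-robin so the stratified split is exercised.
* **Smile prevalence 0.354**: the positive share of a 28-of-79 test half,
  extrapolated to the whole set; configurable, since the true overall
  prevalence of such a study is design-dependent.
* **Smile segments** carry a trapezoidal pulse on the active mouthSmile
  channel(s): 0.5 s rise, 1–3 s plateau, 0.5 s fall, onset uniform in the
  room the pulse leaves, peak drawn from **[0.60, 0.95]**, plus Gaussian
  frame jitter (sd 0.02, clipped to $[0,1]$); the apex frame is pinned to
  the drawn peak so the per-segment maximum never falls below the class
  gap. With probability **0.2** the smile is one-sided. Any smooth unimodal
  pulse satisfies the contract; the trapezoid is the simplest to reason
  about.
* **Neutral segments** carry bounded uniform noise in **[0.00, 0.30]** on
  the mouthSmile channels. The smile and neutral amplitude ranges are
  disjoint by construction, so the training ROC must reach AUC = 1 and the
  Youden threshold must land in the open gap between the realized neutral
  maximum and smile minimum — this is what makes threshold recovery a
  *testable* property.
* **cheekSquint channels** replay the same event attenuated by **0.55**
  with frame noise sd **0.12**. These two values were calibrated once, by
  a seed-averaged grid scan, so that a cheekSquint-only classifier attains
  AUC ≈ 0.95–0.97: informative but clearly weaker than mouthSmile,
  reproducing the qualitative ordering of the two action units.
* **Rater panel**: 5 raters independently copy the true label, flipping
  with probability **0.016**, under which Fleiss' $\kappa$ concentrates
  near 0.91 for $n = 158$ — a panel with high but imperfect agreement
  whose majority vote rarely deviates from truth.

What the generator does **not** emulate: head-pose and occlusion
artifacts, temporal autocorrelation of tracking noise, rater errors that
correlate across raters or depend on smile intensity, and participant-level
heterogeneity in expressiveness. Passing tests therefore demonstrate that
the pipeline's statistics and decision rules are correct, not that the
classifier would reach the same operating characteristics on real
recordings.

```{r pipeline}
res <- run_smile_pipeline(seed = 7)
res$rater_agreement
res$classifier
roc_auc(res$roc)
res$report
```

## Numerical choices and degenerate inputs

* Blendshape values are validated to $[0,1]$ inclusive; exact 0 and 1 are
  legal.
* Frame indices are 0-based; time is derived as `frame_index / fps` and
  never stored.
* Single-class truth makes TPR or FPR undefined: `roc_curve()` errors
  rather than returning a degenerate curve.
* Majority votes on even panels raise on ties unless a tie policy is
  supplied; the default 5-rater panel cannot tie.
* Both kappas signal "undefined" (an error, not `NaN`) when chance
  agreement is 1.
* All generators draw from R's RNG under `withr::with_seed`, so identical
  seeds give bitwise-identical datasets and byte-identical pipeline
  artifacts on disk.

## Problem sizes used by the test suite

The property tests run at sizes chosen to make the checks sharp but quick:
200 random tie-free instances ($n \le 50$) for the AUC–concordance
identity, 100 generator seeds for threshold recovery and split integrity,
200 simulated panels for the Fleiss calibration band, and 50 random
confusion tables for the Cohen cross-check against the determinant
identity $\kappa = 2(TP \cdot TN - FP \cdot FN) / [(TP+FP)(FP+TN) +
(TP+FN)(FN+TN)]$.

## Limitations

The package evaluates *segment-level* classification only: it does not
localize smile events within a segment, fuse more than one action-unit
pair, or model rater-specific bias. The Fleiss interval rests on a
large-sample approximation that is optimistic for $n$ in the low hundreds
with agreement near 1; the Cohen interval is a Wald interval with the
same caveat. Both are reported untruncated by design.
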