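---
title: "Methods: weighted-Euclidean scaling of arrangement data in spamscal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted-Euclidean scaling of arrangement data in spamscal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spamscal)
```

## The data model

A *proximity matrix* is one subject's square, symmetric, zero-diagonal
table of non-negative dissimilarities over an item set — either
centre-to-centre pixel distances from a spatial arrangement (SpAM) trial,
or pairwise Likert dissimilarity ratings. A *proximity stack* aligns one
such matrix per subject over the identical item set; items are
canonicalized to lexicographic order (or an explicit order the user
supplies) so that permuted inputs build identical stacks. Screen
coordinates follow the display convention (origin top-left, y downward);
only relative distances propagate, so the convention is internal. Distances
are taken between item centres; nothing in arrangement data records item
extents, so centre-to-centre is the only defensible choice.

## The scaling model and its assumptions

We fit the weighted-Euclidean (INDSCAL-type) model: a single group
configuration $X \in \mathbb{R}^{n\times k}$ and per-subject non-negative
dimension weights $w_s$, with model distances

$$ d_{ij}^{(s)} = \Big(\sum_{a=1}^{k} w_{sa}\,(x_{ia}-x_{ja})^2\Big)^{1/2}. $$

The model assumes all subjects perceive the same dimensions and differ only
in how strongly they weight them — the standard three-way MDS assumption,
adequate for homogeneous subject pools and checkable after the fact through
the weirdness scores.

Dissimilarities are treated as *ratio-level* (metric) data: each subject's
matrix is meaningful only up to a positive scale factor, because a
participant who uses the full screen and one who clusters items in a corner
express the same structure in different pixel units. Accordingly the
disparities are $\hat d^{(s)} = b_s\,\delta^{(s)}$ with $b_s \ge 0$ fitted
per subject (matrix-conditional). Internally each subject's disparity
vector is scaled to a fixed sum of squares; this is the same transformation
family, and the fixed norm removes the degenerate global optimum of the
ratio model (shrinking both $b_s$ and $X$ to zero). The reported
`disparity_slope` $b_s$ is recovered afterwards by regressing the final
model distances on the raw dissimilarities through the origin.

### Stress

Fit is monitored and reported as Kruskal's stress formula 1 on the pooled
(all subjects) disparity/distance vectors,

$$ S = \sqrt{\frac{\sum_{s}\sum_{i<j}(\hat d_{ij}^{(s)} - d_{ij}^{(s)})^2}
                  {\sum_{s}\sum_{i<j}\hat d_{ij}^{(s)2}}}, $$

normalized by the disparities. Two normalizations of stress-1 circulate in
the scaling literature (by the squared disparities, or by the squared model
distances); we use the disparity-normalized form, for three reasons: it is
bounded by 1 for any non-negative fit (a doubled disparity vector fitted by
the same distances has stress exactly 0.5, which matches how practitioners
read the statistic); it is the form whose null-data values fall in the
range classical ALSCAL-family programs print for random data; and under our
fixed-norm disparities its denominator is constant, which makes the
monotone-convergence guarantee below exact. Per-subject stress is reported
alongside, with the same formula restricted to one subject. A single pooled
headline value per solution matches the usual one-number-per-dataset
reporting; per-subject values support outlier screening.

### Variance accounted for

$R^2$ is the squared product-moment correlation between a subject's raw
dissimilarities and their model distances, averaged over subjects. A
zero-variance dissimilarity vector leaves that subject's correlation
undefined; such subjects are dropped from the average with a warning. Note
that for pure-noise data $R^2$ is still positive and grows with $k$: each
subject's $k$ free weights let the model chase some of that subject's
noise. This overfitting-driven floor is precisely what the Monte Carlo
baseline quantifies.

## The optimizer

Given disparities, the coordinate/weight subproblem is solved by
majorization: for each subject, a Guttman transform of the personal
configuration $Y_s = X\,\mathrm{diag}(\sqrt{w_s})$ produces a target
$\bar Y_s$; the constrained update then alternates two closed-form
column-wise least-squares steps that project the targets back onto the
shared-configuration structure ($X$ given the weights, then each subject's
weights given $X$, clamped at zero), followed by one optimal global
rescaling of $X$. Every step is non-increasing in the pooled residual sum
of squares, hence — with the fixed disparity norm — in stress-1; the
iteration log (`stress_path`) asserts this at run time.

One user-facing iteration runs this majorization phase to internal
stability (improvement below $10^{-6}$, capped at 200 cycles), mirroring
the complete conditional solves of classic alternating least squares. The
outer alternation then applies the three standard termination criteria:
stress failing to decrease by more than `stress_delta_tol` (default .001),
stress below `stress_floor` (default .005), or `max_iter` (default 30)
iterations. With ratio-level disparities the outer loop typically
terminates on the first criterion after one or two iterations, because the
fixed-norm disparity transform leaves nothing for later alternations to
renegotiate.

**Initialization.** The default start is deterministic: classical metric
scaling (`cmdscale`, i.e. double-centering and eigendecomposition) of the
subject-averaged disparity matrix, with unit weights. If the averaged
matrix supports fewer than $k$ positive eigenvalues, the missing columns
are padded with small seeded jitter. `n_restarts − 1` further random starts
(seeded standard-normal configurations) are available as an escape hatch
from local minima; the lowest-stress solution wins. The default is a single
deterministic start, so identical inputs give identical output.

**Axis normalization.** On return, columns of $X$ are scaled to unit mean
square, the scale is absorbed into the weights, and columns are ordered by
decreasing mean subject weight, so dimension 1 is the primary dimension and
weights are comparable across subjects and dimensionalities.

**Degenerate input.** An all-zero matrix is rejected. If every off-diagonal
dissimilarity is equal there is no structure to fit; the fit returns a
seeded random configuration with uniform weights and warns, rather than
pretending to converge.

## Weirdness scores

The weirdness score indexes how far subject $s$'s weight profile departs
from the group's: 0 when $w_s$ is proportional to the group-average weight
direction, approaching 1 as $w_s$ approaches a coordinate axis. We use an
angular form: $\theta_s / \theta_{\max}$, where $\theta_s$ is the angle
between $w_s$ and the mean of the subjects' unit weight vectors, and
$\theta_{\max}$ is the largest angle any non-negative vector can make with
that mean (attained on the coordinate axis with the smallest mean weight).
Averaging unit vectors (rather than raw rows) makes the score exactly
invariant to rescaling any single subject's row, which the ratio model
demands. The score is undefined for one-dimensional solutions — with one
weight per subject every profile is proportional to every other — and the
package refuses to compute it there. Historical SPSS ALSCAL printed a
weirdness index whose exact normalization was never fully documented; our
formula satisfies every property stated for that index but can differ
numerically.

## Classification products

**Pair-similarity continuum.** All $n(n-1)/2$ pair distances in the group
space (unit weights — the products describe the aggregate space, not any
one subject) are ranked ascending and ternary-split into close/mid/far.
When $N$ is not divisible by 3 the leftover one or two slots go to *close*
first, then *mid* — so 136 pairs split 46/45/45 and 17 items split 6/6/5. A
fixed, documented remainder rule keeps the classification reproducible;
any other convention would differ only in boundary cases. Distance ties are
broken by canonical item order (stable), so classes never depend on
floating-point sort order.

**Centrality.** Each item's mean distance to all other items, ranked
ascending (rank 1 = most central) and split inner/mid/outer by the same
rule.

**Agreement curves.** For each dimensionality $k$, the mean Pearson
correlation between its pair-distance vector (or per-item mean-distance
vector) and those of the other fitted dimensionalities; the ordinal mode
correlates fractional ranks, i.e. equals the Spearman correlation of the
raw vectors. Raw and ordinal modes are both provided because raw distances
are the more sensitive measure while ranks are robust to monotone
distortion.

## Monte Carlo null models

Two generators produce data with no shared structure:

* `spam` — each simulated subject places 17 items independently and
  uniformly on a 1366 × 768 plane (the full monitor area, mirroring the
  displays arrangement data are typically collected on) and contributes the
  planar pixel-distance matrix. No minimum-separation constraint is
  imposed: the emulated null subject drags items anywhere, including on top
  of each other.
* `pairwise` — each unordered pair receives an independent uniform integer
  rating on a 1–9 Likert scale, treated as a dissimilarity. The 1–9 integer
  support is our choice of a representative Likert protocol; simulated
  ratings on other bounded supports behave equivalently after the ratio
  transform.

The two generators differ in one structural respect: planar distance
matrices always satisfy the triangle inequality, while independently rated
pairs almost surely violate it. That metric-integrity gap, not any shared
similarity structure, is why pairwise null data scale slightly worse than
arrangement null data.

Defaults are 20 replicate simulations of 20 subjects and 17 items per
generator, scaled in dimensionalities 1–5 — the design whose group means
the acceptance script reproduces. Replicate RNG streams are spawned from
one master seed, so batches are bit-reproducible and replicates independent
of execution order.

A third, *structured* generator (`simulate_structured`, also available as
the `simulate()` method of a fit) plants a known configuration and weight
matrix, adds zero-truncated Gaussian noise to the implied distances, and is
the package's parameter-recovery harness: with zero noise a fit must
recover the planted distances essentially exactly, and recovered stress
must grow with the planted noise level. The test suite asserts both.

**What the null models do and do not show.** Passing reproduction checks on
these generators demonstrates that the estimator behaves correctly on data
with known (absent or planted) structure. The generators deliberately omit
features of real arrangement data — item-size constraints, edge avoidance,
deliberate cluster spacing, rating drift over trials — so null-model
results calibrate a baseline, not a model of human behaviour.

## Numerical choices and limitations

* Long-format input tolerates a relative asymmetry of $10^{-9}$ between
  the (a, b) and (b, a) records of a pair; anything larger indicates
  corrupt input and is rejected, as are duplicated ordered pairs.
* Stress monotonicity is guaranteed within a fit; across dimensionalities
  it is expected but not enforced — a higher-dimensional local minimum can
  (rarely) exceed a lower-dimensional one, which the profile reports as a
  message rather than an error.
* One-dimensional scaling is the classic hard case for any
  distance-majorization method; `n_restarts` exists chiefly for it. The
  bundled oracle test checks the 1-D optimizer against a dense grid search
  for four items.
* Converged alternating-least-squares fits of the stress-aligned loss
  differ from historical SPSS ALSCAL output in a known direction: ALSCAL
  minimizes s-stress (squared distances), so its reported stress-1 values
  for null data sit visibly above the optimum of stress-1 itself, its
  subject weights stay more diffuse, and its solutions agree less across
  dimensionalities. Our fits reach lower stress, concentrate weights more
  (higher weirdness on intrinsically two-dimensional arrangement nulls) and
  agree more across dimensionalities. These differences are inherent to the
  loss functions, not convergence artifacts; degrading the optimizer to
  match historical output would be the wrong trade.
* Test problem sizes: unit and property tests run on 4–17 items and 1–10
  subjects with planted or null data; the reproduction checks run the full
  20 × 20 × 17 design. These sizes were chosen so the whole suite exercises
  every code path at the scale the method is used in practice.
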