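# spamscal

Individual-differences multidimensional scaling for spatial-arrangement
similarity data.

## What this is for

In the spatial arrangement method (SpAM), a participant drags pictures of
objects around a screen so that similar objects end up close together; the
pairwise pixel distances between the placed items form that participant's
dissimilarity matrix. `spamscal` turns such arrangements (or ordinary
pairwise Likert dissimilarity ratings) into aligned proximity stacks, embeds
them in a shared low-dimensional "psychological space", and derives the
classification products analysts build on top of such spaces. It is aimed
at researchers in perception, categorization and psycholinguistics who
collect similarity judgements over moderate item sets (roughly 10–30 items,
any number of participants).

## The model

The core is metric three-way MDS in the INDSCAL family, fitted by
alternating least squares. All subjects share one configuration
`X` (items × k), and subject *s* stretches its axes with non-negative
weights `w_s`:

    d_ij^(s) = sqrt( sum_a  w_sa (x_ia − x_ja)^2 )

Dissimilarities are treated as ratio-level data (each subject's matrix
enters only up to a positive scale factor, since screen usage sets an
arbitrary unit), so the disparities are `dhat^(s) = b_s δ^(s)` with
`b_s ≥ 0`. Fit quality is monitored with Kruskal's stress formula 1,

    S = sqrt( sum (dhat_ij − d_ij)^2 / sum dhat_ij^2 )

pooled over subjects, and iteration stops when stress fails to decrease by
more than .001, falls below .005, or 30 iterations have run. Each iteration
solves the coordinate/weight subproblem by majorization (a Guttman
transform per subject followed by projection onto the weighted-Euclidean
structure), run to internal stability, so reported stress is
non-increasing.

On top of a fitted solution the package computes:

* **R² / VAF** — squared disparity–distance correlation per subject,
  averaged;
* **weirdness scores** — per-subject index in [0, 1] of how far a subject's
  dimension-weight profile departs from the group-average direction (0 =
  proportional to the average; → 1 near a coordinate axis); undefined for
  k = 1;
* **pair-similarity continuum** — all item pairs ranked by group-space
  distance and ternary-split into close / mid / far;
* **prototypicality (centrality)** — items ranked by mean distance to all
  other items and split into inner / mid / outer;
* **agreement curves** — for each dimensionality, the mean Pearson
  correlation of its inter-item distance (or rank) vector with those of the
  other dimensionalities;
* **Monte Carlo null models** — batches of random data with no shared
  structure, generated either as random screen arrangements (`spam`) or as
  independent uniform Likert ratings per pair (`pairwise`), used as an
  objective baseline for scaling quality.

## Worked example

```r
library(spamscal)

# a small stack of simulated SpAM subjects: 8 items, 6 subjects
stack <- simulate_null_stack(null_spec("spam", n_items = 8, n_subjects = 6,
                                       seed = 42))
fit <- indscal(stack, dims = 2, seed = 42)
fit
#> Weighted-Euclidean MDS (INDSCAL-type), k = 2
#>   8 items, 6 subjects
#>   stress-1 = 0.4077, R^2 = 0.3764
#>   2 iteration(s), stopped on 'delta'

head(pair_table(fit), 3)
#>   item_a item_b distance rank class
#> 1 item01 item02 1.756441   11   mid
#> 2 item01 item03 2.383191   20   far
#> 3 item01 item04 1.227558    4 close

round(weirdness(fit), 3)
#>   s01   s02   s03   s04   s05   s06
#> 0.172 0.010 0.931 0.413 0.582 0.510
```

Because these six "subjects" placed the items at random, the stack has no
shared structure: stress is high for a 2-D solution of only 8 items, R² is
low, and several weirdness scores are large (the fitted dimension weights
disagree across subjects). Real, structured data yield low stress, high R²,
and weirdness concentrated near zero; `run_null_batch()` /
`compare_batches()` formalize that contrast, and `run_scale()` writes the
full artifact set (coordinates, weights, classification tables, agreement
curves, scree data, manifest) for a stack of your own data read with
`read_proximity()`.

A command-line wrapper with `scale` and `simulate` subcommands is installed
at `inst/cli/spamscal.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "spamscal.R", package = "spamscal"))')" \
    simulate --method both --n-sims 20 --out results/nulls --seed 1
```

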