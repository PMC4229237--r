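## ternary split of N ranked things: base floor(N/3); leftover 1-2 slots go
## to the first class, then the middle one (136 -> 46/45/45, 17 -> 6/6/5)
.ternary_sizes <- function(N) {
  base <- N %/% 3
  rem <- N - 3 * base
  c(base + (rem >= 1), base + (rem >= 2), base)
}

.ternary_class <- function(ranks, labels) {
  sizes <- .ternary_sizes(length(ranks))
  cuts <- cumsum(sizes)
  cls <- labels[findInterval(ranks, c(0, cuts), left.open = TRUE)]
  factor(cls, levels = labels)
}

## stable competition-free ranks: ties broken by canonical (input) order
.stable_rank <- function(x) {
  r <- integer(length(x))
  r[order(x)] <- seq_along(x)
  r
}

#' Pair-similarity continuum
#'
#' MDS coordinates carry no unit, so absolute cutoffs for "very similar"
#' cannot be defined; instead every unordered item pair is ranked by its
#' Euclidean distance in the group space (unit weights) and classified by a
#' ternary split of the ranking into `close`, `mid` and `far` pairs. Rank 1
#' is the most similar (closest) pair. When the number of pairs is not
#' divisible by three, the leftover slots go to `close` first, then `mid`,
#' so class sizes differ by at most one. Distance ties are broken by
#' canonical item order, making the classification reproducible.
#'
#' @param solution an `"indscal"` fit, or a coordinate matrix (items x
#'   dimensions, labelled rows).
#' @return a data frame of class `"pair_table"` with columns `item_a`,
#'   `item_b`, `distance`, `rank`, `class`; n(n-1)/2 rows.
#' @examples
#' X <- cbind(c(0, 1, 3, 7)); rownames(X) <- letters[1:4]
#' pair_table(X)
#' @export
pair_table <- function(solution) {
  X <- if (inherits(solution, "indscal")) solution$X else as.matrix(solution)
  n <- nrow(X)
  d <- weighted_distances(X)
  idx <- .pair_index(n)
  dv <- d[idx]
  rank <- .stable_rank(dv)
  out <- data.frame(item_a = rownames(X)[idx[, 2]],
                    item_b = rownames(X)[idx[, 1]],
                    distance = dv, rank = rank,
                    class = .ternary_class(rank, c("close", "mid", "far")),
                    stringsAsFactors = FALSE)
  class(out) <- c("pair_table", "data.frame")
  out
}

#' Item prototypicality (centrality)
#'
#' Prototypical items sit near the centre of the psychological space. Each
#' item's mean Euclidean distance to every other item in the group space is
#' computed; items are ranked (rank 1 = smallest mean distance = most
#' central) and ternary-split into `inner`, `mid` and `outer` classes with
#' the same remainder rule and tie-break as [pair_table()].
#'
#' @inheritParams pair_table
#' @return a data frame of class `"centrality_table"` with columns `item`,
#'   `mean_distance`, `rank`, `class`; one row per item.
#' @export
centrality_table <- function(solution) {
  X <- if (inherits(solution, "indscal")) solution$X else as.matrix(solution)
  n <- nrow(X)
  d <- weighted_distances(X)
  md <- rowSums(d) / (n - 1)
  rank <- .stable_rank(md)
  out <- data.frame(item = rownames(X), mean_distance = unname(md),
                    rank = rank,
                    class = .ternary_class(rank, c("inner", "mid", "outer")),
                    stringsAsFactors = FALSE)
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Cross-dimensionality agreement curves
#'
#' How consistent is the spatial organization across solutions of different
#' dimensionality? For each dimensionality k the inter-item distance vector
#' (basis `"pairs"`) or the per-item mean-distance vector (basis
#' `"centrality"`) is correlated (Pearson) with the corresponding vector of
#' every other dimensionality, and the correlations are averaged. Mode
#' `"raw"` correlates the distances themselves; mode `"ordinal"` correlates
#' fractional (mid) ranks, which equals the Spearman correlation of the raw
#' vectors. A zero-variance vector leaves its correlations undefined; they
#' are dropped from the mean with a warning.
#'
#' @param profile an [indscal_profile()].
#' @param mode `"raw"` or `"ordinal"`.
#' @param basis `"pairs"` or `"centrality"`.
#' @return a data frame of class `"agreement_curve"` with columns `dims`,
#'   `mean_r`, `mode`, `basis`; attribute `"cor_matrix"` holds the full
#'   cross-dimensionality correlation matrix.
#' @export
agreement_curves <- function(profile, mode = c("raw", "ordinal"),
                             basis = c("pairs", "centrality")) {
  stopifnot(inherits(profile, "indscal_profile"))
  mode <- match.arg(mode)
  basis <- match.arg(basis)
  vecs <- vapply(profile$solutions, function(fit) {
    if (basis == "pairs") pair_table(fit)$distance
    else centrality_table(fit)$mean_distance
  }, numeric(if (basis == "pairs")
    length(profile$solutions[[1]]$items) *
      (length(profile$solutions[[1]]$items) - 1) / 2
    else length(profile$solutions[[1]]$items)))
  if (mode == "ordinal") vecs <- apply(vecs, 2, rank)  # fractional ranks
  cm <- suppressWarnings(stats::cor(vecs))
  diag(cm) <- NA
  if (anyNA(cm[upper.tri(cm)]))
    warning("zero-variance vector: undefined correlations dropped from means")
  mean_r <- rowMeans(cm, na.rm = TRUE)
  out <- data.frame(dims = profile$dims, mean_r = unname(mean_r),
                    mode = mode, basis = basis, stringsAsFactors = FALSE)
  attr(out, "cor_matrix") <- cm
  class(out) <- c("agreement_curve", "data.frame")
  out
}
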