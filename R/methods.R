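#' @export
print.indscal <- function(x, ...) {
  cat(sprintf("Weighted-Euclidean MDS (INDSCAL-type), k = %d\n", x$dims))
  cat(sprintf("  %d items, %d subjects\n", length(x$items), length(x$subjects)))
  cat(sprintf("  stress-1 = %.4f, R^2 = %.4f\n", x$stress1, x$rsq))
  cat(sprintf("  %d iteration(s), stopped on '%s'\n", x$n_iter, x$stop_reason))
  invisible(x)
}

#' @export
summary.indscal <- function(object, ...) {
  out <- list(dims = object$dims, n_items = length(object$items),
              n_subjects = length(object$subjects),
              stress1 = object$stress1, rsq = object$rsq,
              stress_by_subject = object$stress_by_subject,
              rsq_by_subject = object$rsq_by_subject,
              weight_means = colMeans(object$W),
              weirdness = if (object$dims >= 2) weirdness(object) else NULL,
              n_iter = object$n_iter, stop_reason = object$stop_reason)
  class(out) <- "summary.indscal"
  out
}

#' @export
print.summary.indscal <- function(x, ...) {
  cat(sprintf("Weighted-Euclidean MDS, k = %d (%d items, %d subjects)\n",
              x$dims, x$n_items, x$n_subjects))
  cat(sprintf("Pooled stress-1: %.4f   mean R^2: %.4f\n", x$stress1, x$rsq))
  cat(sprintf("Converged after %d iteration(s) on criterion '%s'\n",
              x$n_iter, x$stop_reason))
  cat("\nMean dimension weights:\n")
  print(round(x$weight_means, 4))
  cat("\nPer-subject fit:\n")
  tab <- data.frame(stress1 = round(x$stress_by_subject, 4),
                    rsq = round(x$rsq_by_subject, 4))
  if (!is.null(x$weirdness)) tab$weirdness <- round(x$weirdness, 4)
  print(tab)
  invisible(x)
}

#' @export
coef.indscal <- function(object, what = c("coordinates", "weights"), ...) {
  switch(match.arg(what), coordinates = object$X, weights = object$W)
}

#' Model distances of a fitted solution
#'
#' `fitted()` returns each subject's model distances (the weighted-Euclidean
#' distances implied by the group space and that subject's weights) as a
#' subjects x pairs matrix; `residuals()` returns disparities minus model
#' distances on the same layout.
#'
#' @param object an `"indscal"` fit.
#' @param ... unused.
#' @return numeric matrix, subjects x item pairs (columns labelled
#'   `"a:b"` in canonical item order).
#' @export
fitted.indscal <- function(object, ...) {
  out <- object$model_dist
  idx <- .pair_index(length(object$items))
  dimnames(out) <- list(object$subjects,
                        paste(object$items[idx[, 2]],
                              object$items[idx[, 1]], sep = ":"))
  out
}

#' @rdname fitted.indscal
#' @export
residuals.indscal <- function(object, ...) {
  f <- fitted(object)
  r <- object$dhat - object$model_dist
  dimnames(r) <- dimnames(f)
  r
}

#' Predict model distances for new subject weights
#'
#' Evaluates the weighted-Euclidean distance model on the fitted group
#' configuration with arbitrary non-negative dimension weights.
#'
#' @param object an `"indscal"` fit.
#' @param weights non-negative weight vector (length k) or matrix
#'   (subjects x k); default unit weights, i.e. the group-space distances.
#' @param ... unused.
#' @return one symmetric distance matrix (vector weights) or a list of them.
#' @export
predict.indscal <- function(object, weights = NULL, ...) {
  if (is.null(weights)) weights <- rep(1, object$dims)
  if (is.matrix(weights))
    return(lapply(seq_len(nrow(weights)),
                  function(s) weighted_distances(object$X, weights[s, ])))
  weighted_distances(object$X, weights)
}

#' @export
plot.indscal <- function(x, dims = c(1, 2), ...) {
  if (x$dims == 1) {
    graphics::stripchart(x$X[, 1], pch = 19, method = "stack",
                         xlab = "Dim1", ...)
    graphics::text(x$X[, 1], 1.05, labels = rownames(x$X), cex = 0.7, srt = 90)
  } else {
    graphics::plot(x$X[, dims[1]], x$X[, dims[2]], pch = 19, asp = 1,
                   xlab = colnames(x$X)[dims[1]],
                   ylab = colnames(x$X)[dims[2]], ...)
    graphics::text(x$X[, dims[1]], x$X[, dims[2]], labels = rownames(x$X),
                   pos = 3, cex = 0.7)
  }
  invisible(x)
}

#' Simulate proximity stacks from a fitted solution
#'
#' Draws new stacks whose subject dissimilarities are the fitted model
#' distances (group space plus each subject's weights) perturbed by
#' Gaussian noise truncated at zero — a parametric-bootstrap companion to
#' [simulate_structured()].
#'
#' @param object an `"indscal"` fit.
#' @param nsim number of stacks to draw.
#' @param seed integer seed (`NULL` leaves the RNG state alone).
#' @param noise_sd standard deviation of the additive noise, in solution
#'   units.
#' @param ... unused.
#' @return a list of `nsim` [proximity_stack()] objects.
#' @export
simulate.indscal <- function(object, nsim = 1, seed = NULL,
                             noise_sd = 0, ...) {
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
  }
  lapply(seq_len(nsim), function(i)
    simulate_structured(object$X, object$W, noise_sd = noise_sd))
}
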