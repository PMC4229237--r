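#' Scaling profile across dimensionalities
#'
#' Fits the weighted-Euclidean model in each requested dimensionality
#' (classically 1-5) on the same stack and assembles the scree data:
#' stress-1 and variance accounted for as a function of dimensionality.
#' Stress typically decreases with each added dimension; a violation is
#' reported as a message, not an error, since alternating least squares
#' carries no cross-dimensional guarantee.
#'
#' @param stack a [proximity_stack()].
#' @param dims integer vector of dimensionalities to fit (default 1:5).
#' @param ... convergence settings passed to [indscal()]
#'   (`stress_delta_tol`, `stress_floor`, `max_iter`, `n_restarts`, `seed`).
#' @return an object of class `"indscal_profile"`: list with `solutions`
#'   (named by dimensionality), `dims`, `stress_by_dim`, `rsq_by_dim`.
#' @examples
#' stack <- simulate_null_stack(null_spec("spam", n_subjects = 4,
#'                                        n_items = 8, seed = 1))
#' prof <- indscal_profile(stack, dims = 1:3)
#' prof$stress_by_dim
#' @export
indscal_profile <- function(stack, dims = 1:5, ...) {
  dims <- sort(unique(as.integer(dims)))
  sols <- lapply(dims, function(k) indscal(stack, dims = k, ...))
  names(sols) <- as.character(dims)
  stress <- vapply(sols, `[[`, numeric(1), "stress1")
  rsq <- vapply(sols, `[[`, numeric(1), "rsq")
  names(stress) <- names(rsq) <- as.character(dims)
  if (length(stress) > 1 && any(diff(stress) > 1e-6))
    message("stress increased with added dimensions at k = ",
            paste(dims[-1][diff(stress) > 1e-6], collapse = ", "),
            " (local minimum)")
  structure(list(solutions = sols, dims = dims,
                 stress_by_dim = stress, rsq_by_dim = rsq),
            class = "indscal_profile")
}

#' @export
print.indscal_profile <- function(x, ...) {
  cat("Weighted-Euclidean MDS scree profile\n")
  tab <- data.frame(dims = x$dims,
                    stress1 = round(x$stress_by_dim, 4),
                    rsq = round(x$rsq_by_dim, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @describeIn indscal_profile scree plot: stress-1 (solid) and R-squared
#'   (dashed) against dimensionality.
#' @param x an `"indscal_profile"`.
#' @export
plot.indscal_profile <- function(x, ...) {
  graphics::plot(x$dims, x$stress_by_dim, type = "b", pch = 19,
                 ylim = c(0, max(x$stress_by_dim, x$rsq_by_dim)),
                 xlab = "Dimensionality", ylab = "Stress-1 / R-squared", ...)
  graphics::lines(x$dims, x$rsq_by_dim, type = "b", lty = 2, pch = 1)
  graphics::legend("topright", legend = c("stress-1", "R-squared"),
                   lty = c(1, 2), pch = c(19, 1), bty = "n")
  invisible(x)
}
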