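#' Weighted-Euclidean model distances
#'
#' Distances under the individual-differences (INDSCAL) model: subject s
#' perceives the shared configuration X through personal non-negative axis
#' weights w, so that
#' \deqn{d_{ij} = \sqrt{\sum_a w_a (x_{ia} - x_{ja})^2}.}
#'
#' @param X numeric matrix of coordinates, items x dimensions.
#' @param w non-negative weight vector, one entry per dimension. Default:
#'   unit weights (the plain group-space distances).
#' @return symmetric matrix of model distances with zero diagonal.
#' @examples
#' X <- cbind(c(0, 3), c(0, 4))
#' weighted_distances(X)          # 5 off the diagonal
#' weighted_distances(X, c(1, 0)) # dimension 1 only
#' @export
weighted_distances <- function(X, w = rep(1, ncol(X))) {
  X <- as.matrix(X)
  if (length(w) != ncol(X)) stop("one weight per dimension is required")
  if (any(w < 0)) stop("weights must be non-negative")
  Y <- X * rep(sqrt(w), each = nrow(X))
  d <- as.matrix(stats::dist(Y))
  dimnames(d) <- list(rownames(X), rownames(X))
  d
}

#' Kruskal stress formula 1
#'
#' \deqn{S = \sqrt{\sum (\hat d_{ij} - d_{ij})^2 / \sum \hat d_{ij}^2}}
#' where \eqn{\hat d} are the disparities (the ratio-transformed data the
#' model distances are fitted to) and \eqn{d} the model distances. The sum
#' of squared disparities normalizes the residual sum of squares, so a
#' doubled disparity vector fitted by the same distances halves its
#' residual share. Vectors may pool pairs over subjects.
#'
#' @param dhat numeric vector of disparities.
#' @param d numeric vector of model distances, same length.
#' @return the stress-1 value (non-negative scalar).
#' @examples
#' d <- c(1, 2, 3)
#' stress1(2 * d, d)  # sqrt(sum(d^2) / sum((2 * d)^2)) = 0.5
#' @export
stress1 <- function(dhat, d) {
  if (length(dhat) != length(d)) stop("dhat and d must have equal length")
  if (sum(d^2) == 0)
    stop("stress-1 is undefined when all model distances are zero")
  sqrt(sum((dhat - d)^2) / sum(dhat^2))
}

## ---- alternating least-squares engine -------------------------------------
##
## Ratio-level (metric) three-way MDS. Per-subject disparities are the raw
## dissimilarities scaled to a fixed sum of squares (the matrix-conditional
## ratio transform; the fixed norm blocks the degenerate collapse of the
## ratio model). Coordinates and weights are updated by majorization: a
## Guttman transform of each subject's personal configuration, followed by
## projection onto the constraint Y_s = X diag(a_s), a_s >= 0 (alternating
## closed-form column updates), followed by an optimal global rescaling of
## X. Each step is non-increasing in the pooled raw stress, and because
## the disparity norm is held fixed, pooled stress-1 is non-increasing
## as well.

.engine <- function(dhat, n, k, X, A, max_iter, tol, floor) {
  S <- nrow(dhat); P <- ncol(dhat)
  idx <- .pair_index(n)
  pair_dists <- function(X, A) {
    E <- (X[idx[, 1], , drop = FALSE] - X[idx[, 2], , drop = FALSE])^2
    sqrt((A^2) %*% t(E))          # S x P squared-weight distances
  }
  rescale <- function(X, D) {
    cc <- sum(dhat * D) / sum(D * D)
    list(X = cc * X, D = cc * D)
  }
  D <- pair_dists(X, A)
  if (all(D == 0)) {              # collapse guard: jitter and retry
    X <- X + stats::rnorm(length(X), sd = 1e-3)
    D <- pair_dists(X, A)
  }
  r <- rescale(X, D); X <- r$X; D <- r$D
  path <- stress1(as.vector(dhat), as.vector(D))
  ## one majorization cycle: Guttman transforms per subject, projection
  ## onto X diag(a_s), global rescale
  cycle <- function(X, A, D) {
    Ybar <- array(0, c(n, k, S))
    for (s in seq_len(S)) {
      ds <- D[s, ]
      ratio <- ifelse(ds > 0, dhat[s, ] / ds, 0)
      R <- .mat_from_pairs(ratio, n)
      B <- -R; diag(B) <- rowSums(R)
      Ybar[, , s] <- ((B %*% X) / n) * rep(A[s, ], each = n)
    }
    for (pass in 1:2) {
      for (a in seq_len(k)) {
        den <- sum(A[, a]^2)
        if (den > 0) {
          Ya <- matrix(Ybar[, a, ], nrow = n)   # n x S slice
          X[, a] <- (Ya %*% A[, a]) / den
        }
      }
      xss <- colSums(X^2)
      for (s in seq_len(S)) {
        proj <- colSums(X * Ybar[, , s]) / pmax(xss, .Machine$double.eps)
        A[s, ] <- pmax(0, proj)
      }
    }
    D <- pair_dists(X, A)
    if (all(D == 0)) return(NULL)
    r <- rescale(X, D)
    list(X = r$X, A = A, D = r$D)
  }
  stop_reason <- "max_iter"
  n_iter <- 0L
  collapsed <- FALSE
  prev_macro <- path[1]
  for (iter in seq_len(max_iter)) {
    ## complete conditional update: run the majorization phase to internal
    ## stability (as classic ALS solves each conditional problem in full)
    inner_last <- path[length(path)]
    for (cyc in seq_len(200L)) {
      st <- cycle(X, A, D)
      if (is.null(st)) { collapsed <- TRUE; break }
      X <- st$X; A <- st$A; D <- st$D
      s1 <- stress1(as.vector(dhat), as.vector(D))
      path <- c(path, s1)
      done <- inner_last - s1 < 1e-6
      inner_last <- s1
      if (done) break
    }
    if (collapsed) { stop_reason <- "delta"; break }
    s1 <- path[length(path)]
    n_iter <- iter
    if (s1 < floor) { stop_reason <- "floor"; break }
    if (prev_macro - s1 <= tol) { stop_reason <- "delta"; break }
    prev_macro <- s1
  }
  list(X = X, A = A, D = D, stress1 = path[length(path)], path = path,
       n_iter = n_iter, stop_reason = stop_reason)
}

## classical-scaling start from the subject-averaged disparity matrix
.init_config <- function(dhat, n, k, items) {
  avg <- .mat_from_pairs(colMeans(dhat), n, items)
  X <- tryCatch(
    suppressWarnings(stats::cmdscale(stats::as.dist(avg), k = k)),
    error = function(e) NULL)
  if (is.null(X) || !length(X)) X <- matrix(0, n, 0)
  if (ncol(X) < k) {              # degenerate average: pad with small jitter
    sd0 <- max(stats::sd(avg), 1e-6) / 100
    X <- cbind(X, matrix(stats::rnorm(n * (k - ncol(X)), sd = sd0),
                         nrow = n))
  }
  unname(X[, seq_len(k), drop = FALSE])
}

#' Fit individual-differences weighted-Euclidean MDS
#'
#' Metric (ratio-level) three-way multidimensional scaling in the INDSCAL
#' family: all subjects share one stimulus configuration `X` and each
#' stretches its axes by personal non-negative weights. The fit alternates
#' (a) a ratio disparity transform per subject (dissimilarities are treated
#' as ratio-level data, so each subject's matrix enters only up to a
#' positive scale factor), (b) a majorization update of the group
#' coordinates and (c) non-negative least-squares updates of the subject
#' weights, and monitors pooled Kruskal stress-1, which is non-increasing
#' across iterations. Iteration stops when stress fails to decrease by more
#' than `stress_delta_tol`, falls below `stress_floor`, or `max_iter`
#' iterations have run.
#'
#' The default start is deterministic (classical metric scaling of the
#' subject-averaged disparity matrix, unit weights); `n_restarts - 1`
#' additional random starts are drawn from `seed` and the lowest-stress
#' solution is kept. On return the configuration columns are normalized to
#' unit mean square (scale absorbed into the weights) and ordered by
#' decreasing mean subject weight, so dimension 1 is the primary dimension.
#'
#' @param stack a [proximity_stack()], or a single [proximity_matrix()].
#' @param dims target dimensionality k (1 to `n_items - 1`; the classical
#'   use is 1-5).
#' @param stress_delta_tol minimum stress decrease to continue iterating.
#' @param stress_floor stress value below which the fit is accepted.
#' @param max_iter maximum number of ALS iterations.
#' @param n_restarts total number of starts (1 = deterministic start only).
#' @param seed integer seed controlling random starts and degenerate-input
#'   fallbacks; the fit is fully reproducible given the same inputs.
#' @return an object of class `"indscal"` with components
#'   \item{X}{n_items x k group coordinates (unit mean-square columns).}
#'   \item{W}{n_subjects x k non-negative subject weights.}
#'   \item{disparity_slope}{per-subject ratio-regression slope b_s linking
#'     raw dissimilarities to model distances.}
#'   \item{stress1}{pooled Kruskal stress-1 of the solution.}
#'   \item{stress_path}{stress-1 after each accepted iteration.}
#'   \item{stress_by_subject}{per-subject stress-1.}
#'   \item{rsq}{mean squared disparity-distance correlation (VAF).}
#'   \item{rsq_by_subject}{its per-subject components.}
#'   \item{n_iter, stop_reason}{convergence record; `stop_reason` is one of
#'     `"delta"`, `"floor"`, `"max_iter"`.}
#' @examples
#' stack <- simulate_null_stack(null_spec("spam", n_subjects = 4,
#'                                        n_items = 8, seed = 1))
#' fit <- indscal(stack, dims = 2)
#' fit$stress1
#' @export
indscal <- function(stack, dims = 2, stress_delta_tol = 1e-3,
                    stress_floor = 5e-3, max_iter = 30, n_restarts = 1,
                    seed = 1L) {
  if (inherits(stack, "proximity_matrix")) stack <- proximity_stack(list(stack))
  stopifnot(inherits(stack, "proximity_stack"))
  k <- as.integer(dims)
  n <- stack$n_items
  if (k < 1 || k >= n) stop("dims must satisfy 1 <= dims <= n_items - 1")
  if (stress_delta_tol <= 0 || stress_floor <= 0 || max_iter < 1)
    stop("invalid convergence settings")
  delta <- .stack_pairs(stack)            # S x P raw dissimilarities
  P <- ncol(delta); S <- nrow(delta)
  ss <- sqrt(rowSums(delta^2))
  if (any(ss == 0)) stop("all-zero proximity matrix for subject(s): ",
                         paste(names(stack$matrices)[ss == 0], collapse = ", "))
  dhat <- delta * sqrt(P) / ss            # fixed-norm ratio disparities

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  degenerate <- stats::var(as.vector(delta)) == 0
  if (degenerate) {
    warning("all dissimilarities are equal: no structure to fit; ",
            "returning a random configuration with uniform weights")
    X <- matrix(stats::rnorm(n * k), n, k)
    X <- scale(X, scale = FALSE)
    X <- X / rep(sqrt(colMeans(X^2)), each = n)  # so returned W is uniform
    A <- matrix(1, S, k)
    best <- .engine(dhat, n, k, X, A, max_iter = 0,
                    tol = stress_delta_tol, floor = stress_floor)
  } else {
    best <- NULL
    for (r in seq_len(max(1L, n_restarts))) {
      X0 <- if (r == 1) .init_config(dhat, n, k, stack$items)
            else matrix(stats::rnorm(n * k), n, k)
      X0 <- scale(X0, scale = FALSE)
      fit <- .engine(dhat, n, k, X0, matrix(1, S, k),
                     max_iter = max_iter, tol = stress_delta_tol,
                     floor = stress_floor)
      if (is.null(best) || fit$stress1 < best$stress1) best <- fit
    }
  }

  ## normalize axes: unit mean-square columns, scale absorbed into weights
  X <- best$X; A <- best$A
  msq <- sqrt(colMeans(X^2))
  pos <- msq > 0
  X[, pos] <- X[, pos, drop = FALSE] / rep(msq[pos], each = n)
  A[, pos] <- A[, pos, drop = FALSE] * rep(msq[pos], each = S)
  W <- A^2
  ord <- order(colMeans(W), decreasing = TRUE)
  X <- X[, ord, drop = FALSE]; W <- W[, ord, drop = FALSE]
  dimnames(X) <- list(stack$items, paste0("Dim", seq_len(k)))
  dimnames(W) <- list(names(stack$matrices), paste0("Dim", seq_len(k)))

  D <- best$D
  slope <- rowSums(delta * D) / rowSums(delta^2)
  s_by_subj <- sqrt(rowSums((dhat - D)^2) / rowSums(dhat^2))
  rsq_s <- vapply(seq_len(S), function(s) {
    if (stats::sd(delta[s, ]) == 0 || stats::sd(D[s, ]) == 0) NA_real_
    else stats::cor(delta[s, ], D[s, ])^2
  }, numeric(1))
  if (anyNA(rsq_s))
    warning("zero-variance disparity vector for ",
            sum(is.na(rsq_s)), " subject(s); excluded from R^2")
  names(s_by_subj) <- names(rsq_s) <- names(slope) <- names(stack$matrices)

  structure(list(X = X, W = W, disparity_slope = slope,
                 stress1 = best$stress1, stress_path = best$path,
                 stress_by_subject = s_by_subj,
                 rsq = mean(rsq_s, na.rm = TRUE), rsq_by_subject = rsq_s,
                 n_iter = best$n_iter, stop_reason = best$stop_reason,
                 dims = k, items = stack$items,
                 subjects = names(stack$matrices),
                 delta = delta, dhat = dhat, model_dist = D,
                 seed = seed, call = match.call()),
            class = "indscal")
}

#' Subject weirdness scores
#'
#' An index in \[0, 1\] of how far each subject's dimension-weight profile
#' departs from the group-average profile. A subject whose weights are
#' proportional to the group-average weights scores 0; the score approaches
#' 1 as the weight vector approaches a coordinate axis (one large weight,
#' the rest near zero). Scores are invariant to positive rescaling of a
#' subject's weight row, and are undefined for one-dimensional solutions.
#'
#' The score is angle-based: the angle between the subject's weight
#' direction and the group mean weight direction (the average of the
#' subjects' unit weight vectors, so each subject contributes only a
#' direction), divided by the largest angle
#' any non-negative weight vector can make with the mean direction (which
#' is attained on a coordinate axis).
#'
#' @param w an `"indscal"` fit, or a non-negative weight matrix (subjects x
#'   dimensions, k >= 2) with no all-zero row.
#' @return named vector of weirdness scores in \[0, 1\].
#' @export
weirdness <- function(w) {
  if (inherits(w, "indscal")) w <- w$W
  w <- as.matrix(w)
  if (ncol(w) < 2)
    stop("weirdness is undefined for one-dimensional solutions")
  if (any(w < 0)) stop("weights must be non-negative")
  rn <- sqrt(rowSums(w^2))
  if (any(rn == 0)) stop("all-zero weight row(s): ",
                         paste(which(rn == 0), collapse = ", "))
  ## group direction = mean of unit weight rows, so that each subject
  ## enters the average only through its direction; this is what makes the
  ## score exactly invariant to rescaling any single row
  wbar <- colMeans(w / rn)
  bn <- sqrt(sum(wbar^2))
  cosines <- pmin(1, pmax(-1, (w %*% wbar)[, 1] / (rn * bn)))
  theta <- acos(cosines)
  theta_max <- acos(min(wbar) / bn)
  out <- if (theta_max == 0) ifelse(theta > 0, 1, 0) else
    pmin(1, theta / theta_max)
  names(out) <- rownames(w)
  out
}
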