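#' Specification of a null-model simulation
#'
#' Defines one Monte Carlo null condition: data with no shared similarity
#' structure, generated either by the `"spam"` method (each simulated
#' subject places the items uniformly at random on a plane proportional to
#' a 1366x768 monitor; dissimilarities are the 2-D Euclidean pixel
#' distances) or by the `"pairwise"` method (each unordered item pair
#' receives an independent uniform integer Likert dissimilarity rating).
#' Defaults follow the classical design: 20 simulations of 20 subjects and
#' 17 items, Likert support 1-9.
#'
#' Because SpAM matrices are genuine planar distance matrices they always
#' satisfy the triangle inequality (metric "integrity"); independently
#' rated pairs almost surely violate it, which is the mechanism by which
#' pairwise null data scale worse than SpAM null data.
#'
#' @param method `"spam"` or `"pairwise"`.
#' @param n_items items per space.
#' @param n_subjects simulated subjects per stack.
#' @param n_sims replicate stacks per batch.
#' @param plane_width,plane_height placement plane in pixels (spam method).
#' @param likert_min,likert_max integer rating support (pairwise method);
#'   ratings are dissimilarities (larger = less similar).
#' @param seed master seed; per-replicate streams are spawned from it so a
#'   batch is bit-reproducible.
#' @return a list of class `"null_spec"`.
#' @export
null_spec <- function(method = c("spam", "pairwise"), n_items = 17,
                      n_subjects = 20, n_sims = 20,
                      plane_width = 1366, plane_height = 768,
                      likert_min = 1, likert_max = 9, seed = 1L) {
  method <- match.arg(method)
  stopifnot(n_items >= 3, n_subjects >= 1, n_sims >= 1,
            plane_width > 0, plane_height > 0, likert_min < likert_max)
  structure(list(method = method, n_items = as.integer(n_items),
                 n_subjects = as.integer(n_subjects),
                 n_sims = as.integer(n_sims),
                 plane_width = plane_width, plane_height = plane_height,
                 likert_min = as.integer(likert_min),
                 likert_max = as.integer(likert_max),
                 seed = as.integer(seed)),
            class = "null_spec")
}

.null_items <- function(n) sprintf("item%02d", seq_len(n))

#' Draw one null-model subject
#'
#' Generates a single subject's proximity matrix under a [null_spec()]
#' condition, consuming the current RNG stream (seed control belongs to the
#' caller; see [simulate_null_stack()] and [run_null_batch()]).
#'
#' @param spec a [null_spec()].
#' @param subject subject id for the matrix.
#' @return a [proximity_matrix()].
#' @export
simulate_null_subject <- function(spec, subject = "s1") {
  stopifnot(inherits(spec, "null_spec"))
  n <- spec$n_items
  items <- .null_items(n)
  if (spec$method == "spam") {
    arr <- arrangement(x = stats::runif(n, 0, spec$plane_width),
                       y = stats::runif(n, 0, spec$plane_height),
                       items = items, subject = subject,
                       plane_width = spec$plane_width,
                       plane_height = spec$plane_height)
    arrangement_distances(arr)
  } else {
    P <- n * (n - 1) / 2
    v <- sample(spec$likert_min:spec$likert_max, P, replace = TRUE)
    proximity_matrix(.mat_from_pairs(v, n, items), subject = subject)
  }
}

#' Draw one null-model stack
#'
#' A full replicate under a null condition: `n_subjects` independent
#' subjects over a shared item set. With `seed` given (default: replicate 1
#' of the spec's master stream) the stack is reproducible.
#'
#' @param spec a [null_spec()].
#' @param seed integer seed for this stack; `NULL` uses the current RNG
#'   stream.
#' @return a [proximity_stack()].
#' @export
simulate_null_stack <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "null_spec"))
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
  }
  mats <- lapply(seq_len(spec$n_subjects), function(s)
    simulate_null_subject(spec, subject = sprintf("s%02d", s)))
  proximity_stack(mats)
}

#' Structured stack from a planted configuration
#'
#' The parameter-recovery generator: subject s's dissimilarities are the
#' weighted-Euclidean distances of planted coordinates `X` under row s of
#' planted weights `W`, plus Gaussian noise truncated at zero. With
#' `noise_sd = 0` the model holds exactly and a fit should recover the
#' generating distances (stress near zero).
#'
#' @param X planted coordinates, items x dimensions (row names become item
#'   labels; unlabelled rows are labelled automatically).
#' @param W planted non-negative weights, subjects x dimensions.
#' @param noise_sd standard deviation of additive Gaussian noise, in the
#'   units of the planted distances.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return a [proximity_stack()].
#' @export
simulate_structured <- function(X, W, noise_sd = 0, seed = NULL) {
  X <- as.matrix(X); W <- as.matrix(W)
  stopifnot(ncol(X) == ncol(W), noise_sd >= 0, all(W >= 0))
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
  }
  if (is.null(rownames(X))) rownames(X) <- .null_items(nrow(X))
  n <- nrow(X); P <- n * (n - 1) / 2
  mats <- lapply(seq_len(nrow(W)), function(s) {
    d <- weighted_distances(X, W[s, ])
    v <- pmax(0, d[lower.tri(d)] + stats::rnorm(P, sd = noise_sd))
    proximity_matrix(.mat_from_pairs(v, n, rownames(X)),
                     subject = sprintf("s%02d", s))
  })
  proximity_stack(mats)
}

#' Count triangle-inequality violations
#'
#' Checks every ordered item triple (i, j, k) of a proximity matrix for
#' d(i,j) > d(i,k) + d(k,j) beyond a tolerance. Planar-distance (SpAM)
#' matrices have none; independently rated pairs almost surely have some —
#' the metric-integrity contrast between the two null models.
#'
#' @param m a [proximity_matrix()].
#' @param tol slack added to the right-hand side before flagging.
#' @return number of violating unordered triples (counting each triple once
#'   per violated side).
#' @export
triangle_violations <- function(m, tol = 1e-9) {
  n <- nrow(m)
  bad <- 0L
  for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- m[i, j]; b <- m[i, k]; cc <- m[j, k]
    bad <- bad + (a > b + cc + tol) + (b > a + cc + tol) + (cc > a + b + tol)
  }
  as.integer(bad)
}

#' Run a Monte Carlo null batch
#'
#' The full null-model experiment for one condition: for each of
#' `spec$n_sims` replicates, generate a stack, scale it in every requested
#' dimensionality, and collect stress-1, variance accounted for, mean
#' weirdness (dimensionalities >= 2), the four agreement curves
#' (pairs/centrality x raw/ordinal) and the stress reduction from the
#' lowest to the highest dimensionality. Replicate seeds are spawned from
#' the spec's master seed, so results are bit-reproducible and independent
#' of execution order.
#'
#' @param spec a [null_spec()].
#' @param dims dimensionalities to fit per replicate (default 1:5).
#' @param ... convergence settings passed to [indscal()].
#' @return an object of class `"mds_batch"`: list with `spec`, `dims`,
#'   `replicates` (per-replicate metric data frame) and `summary` (a data
#'   frame of `method`, `metric`, `dims`, `mean`, `se`, `n`). Metrics:
#'   `stress`, `rsq`, `weirdness`, `agree_<basis>_<mode>` (per
#'   dimensionality) and `stress_reduction` (per replicate, `dims = NA`).
#' @export
run_null_batch <- function(spec, dims = 1:5, ...) {
  stopifnot(inherits(spec, "null_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  rep_seeds <- sample.int(.Machine$integer.max, spec$n_sims)
  rows <- vector("list", spec$n_sims)
  for (r in seq_len(spec$n_sims)) {
    rows[[r]] <- tryCatch(
      .null_replicate(spec, dims, rep_seeds[r], r, ...),
      error = function(e)
        stop(sprintf("replicate %d failed: %s", r, conditionMessage(e))))
  }
  reps <- do.call(rbind, rows)
  grp <- reps
  grp$dims[is.na(grp$dims)] <- 0L   # keep per-replicate metrics in aggregate
  agg <- stats::aggregate(value ~ metric + dims, data = grp,
                          FUN = function(v) c(mean = mean(v),
                                              se = stats::sd(v) / sqrt(length(v)),
                                              n = length(v)))
  summ <- data.frame(method = spec$method, metric = agg$metric,
                     dims = ifelse(agg$dims == 0L, NA_integer_, agg$dims),
                     mean = agg$value[, "mean"],
                     se = agg$value[, "se"], n = agg$value[, "n"],
                     stringsAsFactors = FALSE)
  structure(list(spec = spec, dims = sort(unique(as.integer(dims))),
                 replicates = reps, summary = summ),
            class = "mds_batch")
}

.null_replicate <- function(spec, dims, stack_seed, rep_id, ...) {
  stack <- simulate_null_stack(spec, seed = stack_seed)
  prof <- suppressMessages(
    indscal_profile(stack, dims = dims, seed = stack_seed, ...))
  ks <- prof$dims
  out <- list(
    data.frame(replicate = rep_id, metric = "stress", dims = ks,
               value = unname(prof$stress_by_dim)),
    data.frame(replicate = rep_id, metric = "rsq", dims = ks,
               value = unname(prof$rsq_by_dim)))
  wk <- ks[ks >= 2]
  if (length(wk))
    out <- c(out, list(data.frame(
      replicate = rep_id, metric = "weirdness", dims = wk,
      value = vapply(as.character(wk), function(k)
        mean(weirdness(prof$solutions[[k]])), numeric(1)))))
  for (basis in c("pairs", "centrality")) for (mode in c("raw", "ordinal")) {
    ac <- agreement_curves(prof, mode = mode, basis = basis)
    out <- c(out, list(data.frame(
      replicate = rep_id, metric = paste("agree", basis, mode, sep = "_"),
      dims = ac$dims, value = ac$mean_r)))
  }
  out <- c(out, list(data.frame(
    replicate = rep_id, metric = "stress_reduction", dims = NA_integer_,
    value = unname(prof$stress_by_dim[1] -
                     prof$stress_by_dim[length(ks)]))))
  do.call(rbind, out)
}

#' @export
print.mds_batch <- function(x, ...) {
  cat(sprintf("Monte Carlo null batch: method '%s', %d sims x %d subjects x %d items\n",
              x$spec$method, x$spec$n_sims, x$spec$n_subjects, x$spec$n_items))
  key <- c("stress", "rsq", "weirdness", "agree_pairs_raw", "stress_reduction")
  for (m in key) {
    v <- x$replicates$value[x$replicates$metric == m]
    cat(sprintf("  %-18s grand mean %.3f\n", m, mean(v)))
  }
  invisible(x)
}

#' Grand means of a batch
#'
#' Averages each metric over dimensionalities and replicates (weirdness
#' over dimensionalities 2 and up only), giving the one-number-per-metric
#' summary used to compare data sources.
#'
#' @param batch an `"mds_batch"`.
#' @return named numeric vector of grand means.
#' @export
batch_grand_means <- function(batch) {
  stopifnot(inherits(batch, "mds_batch"))
  tapply(batch$replicates$value, batch$replicates$metric, mean)[
    unique(batch$replicates$metric)]
}

#' Compare two Monte Carlo batches
#'
#' Tabulates per-metric grand means of two batches side by side with their
#' difference and ordering. Descriptive only: no inferential tests.
#'
#' @param a,b `"mds_batch"` objects fitted over the same dimensionalities.
#' @return data frame of class `"batch_comparison"` with columns `metric`,
#'   `mean_a`, `mean_b`, `difference` (a - b), `lower` (which batch has the
#'   smaller mean).
#' @export
compare_batches <- function(a, b) {
  stopifnot(inherits(a, "mds_batch"), inherits(b, "mds_batch"))
  if (!identical(a$dims, b$dims))
    stop("batches were fitted over different dimensionalities")
  ma <- batch_grand_means(a); mb <- batch_grand_means(b)
  metrics <- intersect(names(ma), names(mb))
  out <- data.frame(metric = metrics,
                    mean_a = unname(ma[metrics]), mean_b = unname(mb[metrics]),
                    difference = unname(ma[metrics] - mb[metrics]),
                    stringsAsFactors = FALSE)
  out$lower <- ifelse(out$difference < 0, a$spec$method,
                      ifelse(out$difference > 0, b$spec$method, "tie"))
  attr(out, "methods") <- c(a = a$spec$method, b = b$spec$method)
  class(out) <- c("batch_comparison", "data.frame")
  out
}
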