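#' Construct a spatial arrangement
#'
#' An arrangement records where one subject placed each item on the screen
#' plane during a spatial-arrangement (SpAM) trial. Coordinates follow the
#' screen convention: origin at the top-left corner, x increasing rightward,
#' y increasing downward, measured in pixels. Only relative distances are
#' used downstream, so the convention is internal.
#'
#' @param x,y numeric vectors of pixel coordinates, one entry per item.
#' @param items character vector of unique item labels, same length as `x`.
#' @param subject single string identifying the subject.
#' @param plane_width,plane_height extent of the placement plane in pixels.
#'   Defaults match a 1366x768 display.
#' @return an object of class `"arrangement"`: a data frame with columns
#'   `item`, `x`, `y` and attributes `subject`, `plane_width`, `plane_height`.
#' @examples
#' arr <- arrangement(x = c(0, 3, 10), y = c(0, 4, 0),
#'                    items = c("a", "b", "c"), subject = "s1")
#' arrangement_distances(arr)
#' @export
arrangement <- function(x, y, items, subject = "s1",
                        plane_width = 1366, plane_height = 768) {
  if (length(x) != length(y) || length(x) != length(items))
    stop("x, y and items must have equal length")
  items <- as.character(items)
  .check_items(items)
  missing_xy <- items[!is.finite(x) | !is.finite(y)]
  if (length(missing_xy))
    stop("missing coordinate for item(s): ", paste(missing_xy, collapse = ", "))
  if (any(x < 0) || any(x >= plane_width) || any(y < 0) || any(y >= plane_height))
    stop("coordinates must lie in [0, plane_width) x [0, plane_height)")
  out <- data.frame(item = items, x = as.numeric(x), y = as.numeric(y),
                    stringsAsFactors = FALSE)
  attr(out, "subject") <- as.character(subject)
  attr(out, "plane_width") <- plane_width
  attr(out, "plane_height") <- plane_height
  class(out) <- c("arrangement", "data.frame")
  out
}

.check_items <- function(items) {
  if (anyDuplicated(items)) stop("item labels must be unique")
  if (any(!nzchar(items)) || anyNA(items)) stop("item labels must be non-empty")
  if (length(items) < 3) stop("at least 3 items are required")
  invisible(items)
}

#' Pairwise pixel distances of an arrangement
#'
#' Converts a spatial arrangement to a proximity (dissimilarity) matrix of
#' centre-to-centre 2-D Euclidean distances in pixels. The result is a
#' genuine planar embedding, so it is symmetric, has a zero diagonal and
#' satisfies the triangle inequality.
#'
#' @param arr an [arrangement()].
#' @return a [proximity_matrix()] in pixel units.
#' @export
arrangement_distances <- function(arr) {
  stopifnot(inherits(arr, "arrangement"))
  d <- as.matrix(stats::dist(cbind(arr$x, arr$y)))
  dimnames(d) <- list(arr$item, arr$item)
  proximity_matrix(d, subject = attr(arr, "subject"))
}

#' Construct a proximity matrix
#'
#' A proximity matrix holds one subject's square symmetric dissimilarity
#' table over a fixed item set: pixel distances from a spatial arrangement,
#' or Likert dissimilarity ratings. Larger values always mean less similar.
#'
#' @param values square numeric matrix with item labels as dimnames;
#'   symmetric, zero diagonal, non-negative off-diagonal entries.
#' @param subject single string identifying the subject.
#' @param tol absolute tolerance for the symmetry and zero-diagonal checks.
#' @return the validated matrix with class `"proximity_matrix"` and a
#'   `subject` attribute.
#' @export
proximity_matrix <- function(values, subject = "s1", tol = 1e-8) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("proximity matrix must be square")
  if (is.null(rownames(values)) && is.null(colnames(values)))
    dimnames(values) <- list(paste0("item", seq_len(nrow(values))),
                             paste0("item", seq_len(nrow(values))))
  if (is.null(rownames(values))) rownames(values) <- colnames(values)
  if (is.null(colnames(values))) colnames(values) <- rownames(values)
  if (!identical(rownames(values), colnames(values)))
    stop("row and column item labels must agree")
  .check_items(rownames(values))
  if (!is.numeric(values) || anyNA(values)) stop("all cells must be numeric")
  sc <- max(abs(values), 1)
  if (max(abs(values - t(values))) > tol * sc)
    stop("proximity matrix is not symmetric")
  values <- (values + t(values)) / 2
  if (max(abs(diag(values))) > tol * sc) stop("diagonal must be zero")
  diag(values) <- 0
  if (any(values < 0)) stop("dissimilarities must be non-negative")
  attr(values, "subject") <- as.character(subject)
  class(values) <- c("proximity_matrix", class(values))
  values
}

#' @export
print.proximity_matrix <- function(x, ...) {
  cat(sprintf("Proximity matrix: subject '%s', %d items\n",
              attr(x, "subject"), nrow(x)))
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

#' Subject label of a proximity matrix
#' @param m a proximity matrix.
#' @return the subject id string.
#' @export
subject_id <- function(m) attr(m, "subject")

#' Assemble aligned proximity matrices into a stack
#'
#' A proximity stack is the three-way input to individual-differences
#' scaling: one proximity matrix per subject, all over the identical item
#' set. Items are put into a canonical order (lexicographic by label unless
#' `items` supplies an explicit order) and every matrix is reordered to it,
#' so permuted inputs yield identical stacks.
#'
#' @param matrices list of [proximity_matrix()] objects.
#' @param items optional character vector giving an explicit canonical item
#'   order; default is lexicographic.
#' @return an object of class `"proximity_stack"`: a list with elements
#'   `items`, `matrices` (named by subject), `n_subjects`, `n_items`.
#' @export
proximity_stack <- function(matrices, items = NULL) {
  if (inherits(matrices, "proximity_matrix")) matrices <- list(matrices)
  if (!length(matrices)) stop("at least one matrix is required")
  ref <- sort(rownames(matrices[[1]]))
  if (is.null(items)) items <- ref
  items <- as.character(items)
  .check_items(items)
  if (!setequal(items, ref))
    stop("explicit item order does not match the matrices' item set")
  mats <- vector("list", length(matrices))
  subjects <- character(length(matrices))
  for (s in seq_along(matrices)) {
    m <- matrices[[s]]
    if (!inherits(m, "proximity_matrix")) m <- proximity_matrix(m)
    sid <- attr(m, "subject")
    if (!setequal(rownames(m), items))
      stop(sprintf("item set of subject '%s' does not match the stack", sid))
    mats[[s]] <- m[items, items]
    attr(mats[[s]], "subject") <- sid
    class(mats[[s]]) <- class(m)
    subjects[s] <- sid
  }
  if (anyDuplicated(subjects))
    subjects <- make.unique(subjects, sep = "_")
  names(mats) <- subjects
  structure(list(items = items, matrices = mats,
                 n_subjects = length(mats), n_items = length(items)),
            class = "proximity_stack")
}

#' @export
print.proximity_stack <- function(x, ...) {
  cat(sprintf("Proximity stack: %d subjects x %d items (%d pairs per subject)\n",
              x$n_subjects, x$n_items, x$n_items * (x$n_items - 1) / 2))
  cat("Items:", paste(utils::head(x$items, 8), collapse = ", "),
      if (x$n_items > 8) "..." else "", "\n")
  invisible(x)
}

## lower-triangle pair vector in canonical (stats::dist) order
.pair_index <- function(n) {
  i <- sequence((n - 1):1) + rep(seq_len(n - 1), (n - 1):1)
  j <- rep(seq_len(n - 1), (n - 1):1)
  cbind(i = i, j = j)
}

.pairs_of <- function(m) m[lower.tri(m)]

.mat_from_pairs <- function(v, n, labels = NULL) {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m <- m + t(m)
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

## S x P matrix of pair dissimilarities, rows = subjects
.stack_pairs <- function(stack) {
  do.call(rbind, lapply(stack$matrices, .pairs_of))
}
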