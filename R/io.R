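#' Read proximity data from disk
#'
#' Two dialects are supported. `"square"` is a CSV whose first row and first
#' column hold the item labels and whose cell (i, j) is the dissimilarity
#' between items i and j; it yields a single [proximity_matrix()]. `"long"`
#' is a tab-separated table with columns `subject_id`, `item_a`, `item_b`,
#' `value`; it may list several subjects and only one triangle of each
#' matrix, and yields a named list of proximity matrices (one per subject).
#'
#' In long form, if both (a, b) and (b, a) are present for a subject they
#' must agree to a relative tolerance of 1e-9; distances are deterministic,
#' so a larger asymmetry indicates corrupt input and is rejected, as is a
#' duplicated ordered pair.
#'
#' @param path file to read.
#' @param format `"square"` or `"long"`.
#' @param subject subject id attached to a square-format matrix (default:
#'   the file base name).
#' @return a [proximity_matrix()] (`"square"`) or a named list of them
#'   (`"long"`).
#' @seealso [write_proximity()]
#' @export
read_proximity <- function(path, format = c("square", "long"),
                           subject = NULL) {
  format <- match.arg(format)
  if (format == "square") {
    tab <- utils::read.csv(path, check.names = FALSE, row.names = 1)
    m <- as.matrix(tab)
    if (!is.numeric(m)) stop("non-numeric cell in ", path)
    if (is.null(subject))
      subject <- sub("\\.[^.]*$", "", basename(path))
    return(proximity_matrix(m, subject = subject))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "item_a", "item_b", "value")
  if (!all(need %in% names(tab)))
    stop("long format requires columns: ", paste(need, collapse = ", "))
  if (!is.numeric(tab$value)) stop("non-numeric value cell in ", path)
  out <- lapply(split(tab, tab$subject_id), .long_to_matrix)
  out[unique(tab$subject_id)]
}

.long_to_matrix <- function(df) {
  sid <- df$subject_id[1]
  df <- df[df$item_a != df$item_b, , drop = FALSE]
  key <- paste(df$item_a, df$item_b, sep = "\r")
  if (anyDuplicated(key))
    stop(sprintf("duplicated pair for subject '%s'", sid))
  items <- sort(unique(c(df$item_a, df$item_b)))
  n <- length(items)
  m <- matrix(NA_real_, n, n, dimnames = list(items, items))
  m[cbind(match(df$item_a, items), match(df$item_b, items))] <- df$value
  # reconcile the two triangles
  up <- m; lo <- t(m)
  both <- !is.na(up) & !is.na(lo)
  bad <- both & abs(up - lo) > 1e-9 * pmax(abs(up), abs(lo), 1)
  if (any(bad))
    stop(sprintf("conflicting (a,b)/(b,a) values for subject '%s'", sid))
  m[is.na(up) & !is.na(lo)] <- lo[is.na(up) & !is.na(lo)]
  m[both] <- (up[both] + lo[both]) / 2
  diag(m) <- 0
  if (anyNA(m))
    stop(sprintf("missing pair value(s) for subject '%s'", sid))
  proximity_matrix(m, subject = sid)
}

#' Write a proximity matrix as square CSV
#'
#' Writes the full square matrix with item labels on the first row and
#' column. `read_proximity(path, "square")` reproduces the values exactly
#' (full double precision is kept).
#'
#' @param m a [proximity_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_proximity <- function(m, path) {
  stopifnot(inherits(m, "proximity_matrix"))
  df <- as.data.frame(unclass(m))
  df[] <- lapply(df, function(col) sprintf("%.17g", col))  # exact round-trip
  utils::write.csv(cbind(item = rownames(m), df), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a stack in long TSV form
#'
#' One row per subject and unordered item pair (upper triangle only), with
#' columns `subject_id`, `item_a`, `item_b`, `value`.
#'
#' @param stack a [proximity_stack()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_proximity_long <- function(stack, path) {
  stopifnot(inherits(stack, "proximity_stack"))
  idx <- .pair_index(stack$n_items)
  rows <- lapply(names(stack$matrices), function(sid) {
    m <- stack$matrices[[sid]]
    data.frame(subject_id = sid,
               item_a = stack$items[idx[, "j"]],
               item_b = stack$items[idx[, "i"]],
               value = sprintf("%.17g", m[idx]), stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
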