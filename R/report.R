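#' Write one fitted solution to disk
#'
#' Emits the solution's coordinates (`coords_k<k>.csv`: item, Dim1..Dimk),
#' subject weights with weirdness (`weights_k<k>.csv`; the weirdness column
#' is omitted for k = 1, where it is undefined) and a JSON fit summary
#' (`solution_k<k>.json`: stress-1, R-squared, iterations, stop reason,
#' seed).
#'
#' @param fit an `"indscal"` fit.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_solution <- function(fit, dir) {
  stopifnot(inherits(fit, "indscal"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  k <- fit$dims
  utils::write.csv(data.frame(item = rownames(fit$X), fit$X,
                              check.names = FALSE),
                   file.path(dir, sprintf("coords_k%d.csv", k)),
                   row.names = FALSE, quote = FALSE)
  wdf <- data.frame(subject = rownames(fit$W), fit$W, check.names = FALSE)
  if (k >= 2) wdf$weirdness <- unname(weirdness(fit))
  utils::write.csv(wdf, file.path(dir, sprintf("weights_k%d.csv", k)),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(dims = k, stress1 = fit$stress1, rsq = fit$rsq,
         n_iter = fit$n_iter, stop_reason = fit$stop_reason,
         seed = fit$seed),
    file.path(dir, sprintf("solution_k%d.json", k)),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Scale a stack end to end and write all artifacts
#'
#' The one-call analysis: fit the weighted-Euclidean model in every
#' requested dimensionality, then write per-dimensionality solutions
#' ([write_solution()]), pair and centrality classification tables
#' (`pair_table_k<k>.csv`, `centrality_table_k<k>.csv`), the four agreement
#' curves in two files (`agreement_pairs.csv`, `agreement_centrality.csv`,
#' each with raw and ordinal modes), scree data (`scree.csv`) and a
#' manifest (`manifest.json`) sufficient to reproduce the run. Runs are
#' deterministic: the same input and seed produce identical artifacts.
#'
#' @param stack a [proximity_stack()], or a path readable by
#'   [read_proximity()].
#' @param out_dir output directory.
#' @param dims dimensionalities to fit (default 1:5). With a single
#'   dimensionality of 1, no weirdness is written (undefined) and a message
#'   says so.
#' @param format input dialect when `stack` is a path.
#' @param seed,... convergence settings passed to [indscal()].
#' @param verbose emit per-dimensionality progress messages.
#' @return the output directory, invisibly.
#' @export
run_scale <- function(stack, out_dir, dims = 1:5,
                      format = c("square", "long"), seed = 1L,
                      verbose = TRUE, ...) {
  if (is.character(stack)) {
    m <- read_proximity(stack, format = match.arg(format))
    stack <- proximity_stack(if (inherits(m, "proximity_matrix")) list(m) else m)
  }
  stopifnot(inherits(stack, "proximity_stack"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prof <- indscal_profile(stack, dims = dims, seed = seed, ...)
  for (k in prof$dims) {
    fit <- prof$solutions[[as.character(k)]]
    if (verbose) message(sprintf("k = %d: stress-1 %.4f, R^2 %.4f",
                                 k, fit$stress1, fit$rsq))
    write_solution(fit, out_dir)
    pt <- pair_table(fit); ct <- centrality_table(fit)
    utils::write.csv(pt, file.path(out_dir, sprintf("pair_table_k%d.csv", k)),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(ct, file.path(out_dir, sprintf("centrality_table_k%d.csv", k)),
                     row.names = FALSE, quote = FALSE)
  }
  if (all(prof$dims < 2))
    message("weirdness scores are undefined for one-dimensional solutions; none written")
  if (length(prof$dims) > 1) {
    for (basis in c("pairs", "centrality")) {
      ac <- rbind(agreement_curves(prof, "raw", basis),
                  agreement_curves(prof, "ordinal", basis))
      utils::write.csv(ac, file.path(out_dir, sprintf("agreement_%s.csv", basis)),
                       row.names = FALSE, quote = FALSE)
    }
  }
  utils::write.csv(data.frame(dims = prof$dims,
                              stress1 = unname(prof$stress_by_dim),
                              rsq = unname(prof$rsq_by_dim)),
                   file.path(out_dir, "scree.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(
    list(task = "scale", dims = prof$dims, seed = seed,
         n_items = stack$n_items, n_subjects = stack$n_subjects,
         items = stack$items, subjects = names(stack$matrices),
         package_version = as.character(utils::packageVersion("spamscal"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run the Monte Carlo null study and write all artifacts
#'
#' Runs [run_null_batch()] for each requested null method, writes each
#' batch summary as tidy CSV (`batch_<method>.csv`: method, metric, dims,
#' mean, se, n), the pairwise comparison table (`comparison.csv`) when both
#' methods run, and a manifest capturing the full specification and seed.
#'
#' @param out_dir output directory.
#' @param method `"spam"`, `"pairwise"` or `"both"`.
#' @param n_sims,n_subjects,n_items,seed null-condition settings (see
#'   [null_spec()]).
#' @param dims dimensionalities fitted per replicate.
#' @param ... convergence settings passed to [indscal()].
#' @param verbose emit per-batch progress messages.
#' @return the output directory, invisibly.
#' @export
run_simulate <- function(out_dir, method = c("both", "spam", "pairwise"),
                         n_sims = 20, n_subjects = 20, n_items = 17,
                         dims = 1:5, seed = 1L, verbose = TRUE, ...) {
  method <- match.arg(method)
  methods <- if (method == "both") c("spam", "pairwise") else method
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  batches <- list()
  for (m in methods) {
    if (verbose) message("running ", m, " null batch (", n_sims, " sims)")
    spec <- null_spec(m, n_items = n_items, n_subjects = n_subjects,
                      n_sims = n_sims, seed = seed)
    batches[[m]] <- run_null_batch(spec, dims = dims, ...)
    utils::write.csv(batches[[m]]$summary,
                     file.path(out_dir, sprintf("batch_%s.csv", m)),
                     row.names = FALSE, quote = FALSE)
  }
  if (length(batches) == 2) {
    cmp <- compare_batches(batches[[1]], batches[[2]])
    utils::write.csv(cmp, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(
    list(task = "simulate", methods = methods, n_sims = n_sims,
         n_subjects = n_subjects, n_items = n_items, dims = dims,
         seed = seed,
         package_version = as.character(utils::packageVersion("spamscal"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
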