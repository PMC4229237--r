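# full-size Monte Carlo batches (20 sims x 20 subjects x 17 items) are
# computed once per test run and shared across test blocks
.batch_cache <- new.env(parent = emptyenv())

full_null_batch <- function(method, seed = 1L) {
  key <- paste(method, seed, sep = "_")
  if (is.null(.batch_cache[[key]]))
    .batch_cache[[key]] <- run_null_batch(null_spec(method, seed = seed))
  .batch_cache[[key]]
}
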