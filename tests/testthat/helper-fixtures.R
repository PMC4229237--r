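# deterministic fixtures built in code

# planted 2-D configuration with 17 items and modest weight spread
planted_config <- function(n_items = 17, k = 2, n_subjects = 5, seed = 11) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  X <- matrix(rnorm(n_items * k), n_items, k)
  rownames(X) <- sprintf("it%02d", seq_len(n_items))
  W <- matrix(runif(n_subjects * k, 0.5, 1.5), n_subjects, k)
  list(X = X, W = W)
}

random_proximity <- function(n = 5, seed = 1, subject = "s1") {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  v <- runif(n * (n - 1) / 2, 0.5, 10)
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m <- m + t(m)
  dimnames(m) <- list(letters[seq_len(n)], letters[seq_len(n)])
  proximity_matrix(m, subject = subject)
}

# tight convergence settings for optimizer-limit checks
deep_cfg <- list(stress_delta_tol = 1e-9, stress_floor = 1e-6, max_iter = 200)
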