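test_that("weighted distances follow the subject-weighted Euclidean formula", {
  X <- cbind(c(0, 3), c(0, 4))
  expect_equal(weighted_distances(X)[1, 2], 5)
  # w = (1, 0): distances depend on dimension 1 only
  expect_equal(weighted_distances(X, c(1, 0))[1, 2], 3)
  expect_error(weighted_distances(X, c(-1, 1)), "non-negative")
  expect_error(weighted_distances(X, 1), "per dimension")

  # elementwise brute force on a random configuration
  set.seed(9)
  Xr <- matrix(rnorm(12), 6, 2)
  for (w in list(c(4, 1), c(1, 1), c(0.3, 2.2))) {
    d <- weighted_distances(Xr, w)
    for (i in 1:5) for (j in (i + 1):6)
      expect_equal(d[i, j], sqrt(sum(w * (Xr[i, ] - Xr[j, ])^2)))
  }
})

test_that("stress-1 matches its formula on hand-evaluated cases", {
  d <- c(1, 2, 3)
  expect_equal(stress1(d, d), 0)
  # disparities fixed at twice the distances
  expect_equal(stress1(2 * d, d), sqrt(sum(d^2) / sum((2 * d)^2)))
  expect_equal(stress1(2 * d, d), 0.5)
  expect_error(stress1(c(1, 2), c(0, 0)), "all model distances")
  expect_error(stress1(1:3, 1:2), "equal length")
})

test_that("noise-free planted data are recovered essentially perfectly", {
  cfg <- planted_config()
  stack <- simulate_structured(cfg$X, cfg$W, noise_sd = 0, seed = 21)
  fit <- do.call(indscal, c(list(stack, dims = 2, seed = 3), deep_cfg))
  expect_lte(fit$stress1, 1e-3)
  expect_gte(fit$rsq, 0.999)
  # model distances match generating distances up to a global scale
  for (s in seq_len(nrow(cfg$W))) {
    gen <- weighted_distances(cfg$X, cfg$W[s, ])
    gen <- gen[lower.tri(gen)]
    got <- fitted(fit)[s, ]
    expect_lt(max(abs(got / sqrt(mean(got^2)) - gen / sqrt(mean(gen^2)))) /
                max(gen / sqrt(mean(gen^2))), 1e-3)
  }
})

test_that("reported stress is monotonically non-increasing over iterations", {
  for (seed in 1:4) {
    stack <- simulate_null_stack(null_spec("spam", n_subjects = 6,
                                           n_items = 10, seed = seed))
    fit <- indscal(stack, dims = 3, seed = seed)
    expect_true(all(diff(fit$stress_path) <= 1e-9))
  }
})

test_that("ALS matches a grid-search oracle for 4 items in one dimension", {
  # independent oracle: with a single subject and ratio disparities, stress
  # at the optimal scale is sqrt(1 - cos^2(delta, e)) where e holds the
  # pairwise gaps |x_i - x_j|; minimize over configurations by dense grid
  # plus simplex refinement
  oracle_stress <- function(delta) {
    pairs <- cbind(c(2, 3, 4, 3, 4, 4), c(1, 1, 1, 2, 2, 3))
    s_of <- function(x234) {
      x <- c(0, x234)
      e <- abs(x[pairs[, 1]] - x[pairs[, 2]])
      if (all(e == 0)) return(1)
      sqrt(max(0, 1 - sum(delta * e)^2 / (sum(delta^2) * sum(e^2))))
    }
    g <- seq(-1, 1, by = 0.05)
    grid <- as.matrix(expand.grid(g, g, g))
    vals <- apply(grid, 1, s_of)
    best <- grid[which.min(vals), ]
    stats::optim(best, s_of, method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 5000))$value
  }
  dist_vec <- function(pos) { d <- as.matrix(dist(pos)); d[lower.tri(d)] }

  # colinear positions 0, 1, 3, 7: embeddable exactly, optimum 0
  # perturbed case: not exactly embeddable in one dimension
  cases <- list(dist_vec(c(0, 1, 3, 7)),
                dist_vec(c(0, 1, 3, 7)) + c(0.4, -0.2, 0.3, 0, -0.3, 0.2))
  for (delta in cases) {
    m <- matrix(0, 4, 4)
    m[lower.tri(m)] <- delta
    m <- m + t(m)
    dimnames(m) <- list(letters[1:4], letters[1:4])
    fit <- do.call(indscal,
                   c(list(proximity_matrix(m), dims = 1, seed = 2,
                          n_restarts = 10), deep_cfg))
    expect_lt(abs(fit$stress1 - oracle_stress(delta)), 1e-3)
  }
})

test_that("fit rejects impossible configurations", {
  m <- random_proximity(4, seed = 2)
  expect_error(indscal(m, dims = 4), "dims must satisfy")
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_error(indscal(proximity_matrix(z), dims = 1), "all-zero")
  expect_error(indscal(m, dims = 2, max_iter = 0), "convergence settings")
})

test_that("all-equal dissimilarities yield a flagged uninformative solution", {
  m <- matrix(1, 5, 5); diag(m) <- 0
  dimnames(m) <- list(letters[1:5], letters[1:5])
  w <- capture_warnings(fit <- indscal(proximity_matrix(m), dims = 2, seed = 4))
  expect_match(w, "no structure", all = FALSE)
  expect_equal(max(fit$W) - min(fit$W), 0)   # uniform weights
  # seeded: reproducible configuration
  fit2 <- suppressWarnings(indscal(proximity_matrix(m), dims = 2, seed = 4))
  expect_identical(fit$X, fit2$X)
})

test_that("weirdness honours its contract", {
  # subject weights equal to the column means score zero
  W <- rbind(c(2, 1), c(2, 1), c(2, 1))
  expect_equal(unname(weirdness(W)), c(0, 0, 0), tolerance = 1e-6)
  # any set of mutually proportional rows scores all zero
  W2 <- rbind(c(2, 1), c(4, 2), c(1, 0.5))
  expect_equal(unname(weirdness(W2)), c(0, 0, 0), tolerance = 1e-6)
  # symmetric departures from a symmetric mean score equally, extremes at 1
  w3 <- weirdness(rbind(c(1, 0), c(0.5, 0.5), c(0, 1)))
  expect_equal(unname(w3[1]), unname(w3[3]))
  expect_gt(w3[1], 0)
  expect_equal(unname(w3[2]), 0, tolerance = 1e-6)
  # range and row-scale invariance
  set.seed(12)
  W4 <- matrix(runif(40, 0.1, 3), 10, 4)
  sc <- weirdness(W4)
  expect_true(all(sc >= 0 & sc <= 1))
  W5 <- W4 * runif(10, 0.2, 5)   # rescale each row
  expect_equal(weirdness(W5), sc, tolerance = 1e-10)
  # rejections
  expect_error(weirdness(cbind(1:3)), "one-dimensional")
  expect_error(weirdness(rbind(c(0, 0), c(1, 1))), "all-zero")
  expect_error(weirdness(rbind(c(-1, 1), c(1, 1))), "non-negative")
})

test_that("variance accounted for rises with dimensionality in expectation", {
  rsq <- matrix(0, 5, 4)
  for (seed in 1:5) {
    stack <- simulate_null_stack(null_spec("spam", n_subjects = 6,
                                           n_items = 10, seed = seed))
    prof <- suppressMessages(indscal_profile(stack, dims = 1:4, seed = seed))
    rsq[seed, ] <- prof$rsq_by_dim
  }
  expect_true(all(diff(colMeans(rsq)) > 0))
})

test_that("scree profile of planted 3-D structure has the expected shape", {
  set.seed(31)
  X <- matrix(rnorm(14 * 3), 14, 3)
  W <- matrix(runif(8 * 3, 0.6, 1.4), 8, 3)
  stack <- simulate_structured(X, W, noise_sd = 0.15, seed = 31)
  prof <- suppressMessages(indscal_profile(stack, dims = 1:5, seed = 31))
  drops <- -diff(prof$stress_by_dim)
  expect_gt(drops[1], max(drops[-1]))          # largest drop from k=1 to k=2
  expect_lt(mean(abs(drops[3:4])), drops[1] / 4)  # plateau after k=3
  expect_equal(names(prof$solutions), as.character(1:5))
})
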