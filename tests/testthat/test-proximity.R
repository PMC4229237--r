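test_that("arrangement distances are planar Euclidean pixel distances", {
  arr <- arrangement(x = c(0, 3, 10), y = c(0, 4, 0),
                     items = c("a", "b", "c"), subject = "s1")
  m <- arrangement_distances(arr)
  expect_s3_class(m, "proximity_matrix")
  expect_equal(m["a", "b"], 5)                       # 3-4-5 triangle
  expect_equal(m["a", "c"], 10)
  expect_equal(unname(diag(m)), c(0, 0, 0))
  expect_equal(subject_id(m), "s1")

  # all items at one point -> all-zero matrix
  same <- arrangement(x = rep(7, 4), y = rep(7, 4), items = letters[1:4])
  expect_true(all(arrangement_distances(same) == 0))

  # 17 items give 136 distinct unordered pair distances
  set.seed(4)
  arr17 <- arrangement(x = runif(17, 0, 1366), y = runif(17, 0, 768),
                       items = sprintf("i%02d", 1:17))
  m17 <- arrangement_distances(arr17)
  expect_equal(sum(lower.tri(m17)), 136)
  expect_equal(length(m17[lower.tri(m17)]), 136)
})

test_that("arrangement validation rejects bad coordinates and items", {
  expect_error(arrangement(c(0, 1), c(0, 1), c("a", "b")), "3 items")
  expect_error(arrangement(c(0, 1, NA), c(0, 1, 2), letters[1:3]), "item")
  expect_error(arrangement(c(0, 1, 2000), c(0, 1, 2), letters[1:3]),
               "plane_width")
  expect_error(arrangement(c(0, 1, 2), c(0, 1, 2), c("a", "a", "b")),
               "unique")
})

test_that("planar distances obey the triangle inequality and scale linearly", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 10
    arr <- arrangement(x = runif(n, 0, 1366), y = runif(n, 0, 768),
                       items = sprintf("i%02d", 1:n))
    m <- arrangement_distances(arr)
    expect_equal(triangle_violations(m), 0L)
    # scaling coordinates by c scales every entry by exactly c
    arr2 <- arrangement(x = arr$x / 2, y = arr$y / 2, items = arr$item)
    expect_equal(unclass(arrangement_distances(arr2)), unclass(m) / 2,
                 ignore_attr = TRUE)
  }
})

test_that("proximity matrix validation enforces the invariants", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(proximity_matrix(bad), "square|3 items")
  m <- matrix(c(0, 1, 2, 1, 0, 3, 2.5, 3, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(proximity_matrix(m), "symmetric")
  m[1, 3] <- 2.5; m[3, 1] <- 2.5; m[1, 1] <- 4
  expect_error(proximity_matrix(m), "diagonal")
  m[1, 1] <- 0; m[1, 2] <- m[2, 1] <- -1
  expect_error(proximity_matrix(m), "non-negative")
})

test_that("stacks canonicalize item order so permuted input builds identically", {
  m1 <- random_proximity(6, seed = 1, subject = "s1")
  m2 <- random_proximity(6, seed = 2, subject = "s2")
  perm <- sample(6)
  m2_perm <- proximity_matrix(unclass(m2)[perm, perm], subject = "s2")
  s_a <- proximity_stack(list(m1, m2))
  s_b <- proximity_stack(list(m1, m2_perm))
  expect_identical(s_a$items, s_b$items)
  expect_equal(s_a$matrices, s_b$matrices)
  expect_equal(s_a$n_subjects, 2L)

  # single matrix is a valid stack
  expect_equal(proximity_stack(list(m1))$n_subjects, 1L)

  # item-set mismatch names the offending subject
  m3 <- random_proximity(5, seed = 3, subject = "odd_one")
  expect_error(proximity_stack(list(m1, m3)), "odd_one")

  # explicit order is honoured
  s_c <- proximity_stack(list(m1), items = rev(sort(rownames(m1))))
  expect_identical(s_c$items, rev(sort(rownames(m1))))
})

test_that("square CSV round-trips exactly", {
  m <- random_proximity(5, seed = 42, subject = "rt")
  path <- withr::local_tempfile(fileext = ".csv")
  write_proximity(m, path)
  m2 <- read_proximity(path, "square", subject = "rt")
  expect_identical(unclass(m2), unclass(m))
})

test_that("long TSV reconstructs symmetric matrices and rejects corrupt input", {
  m1 <- random_proximity(5, seed = 7, subject = "s1")
  m2 <- random_proximity(5, seed = 8, subject = "s2")
  stack <- proximity_stack(list(m1, m2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_proximity_long(stack, path)   # upper triangle only
  mats <- read_proximity(path, "long")
  expect_named(mats, c("s1", "s2"))
  expect_equal(unclass(mats$s1), unclass(m1))
  expect_equal(unclass(mats$s2), unclass(m2))

  # conflicting (a,b)/(b,a) values -> error
  tab <- utils::read.delim(path)
  extra <- data.frame(subject_id = "s1", item_a = tab$item_b[1],
                      item_b = tab$item_a[1], value = tab$value[1] + 1)
  bad <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(rbind(tab, extra), bad, sep = "\t", row.names = FALSE)
  expect_error(read_proximity(bad, "long"), "conflicting")

  # duplicated ordered pair -> error
  dup <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(rbind(tab, tab[1, ]), dup, sep = "\t", row.names = FALSE)
  expect_error(read_proximity(dup, "long"), "duplicated")

  # non-numeric cell -> error
  tab2 <- tab; tab2$value <- as.character(tab2$value); tab2$value[3] <- "oops"
  nn <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab2, nn, sep = "\t", row.names = FALSE)
  expect_error(read_proximity(nn, "long"), "non-numeric")
})
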