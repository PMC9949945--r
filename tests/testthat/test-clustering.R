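make_blobs <- function(centers, n_each, sd = 0.1, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    sweep(matrix(rnorm(n_each * ncol(centers), sd = sd), n_each), 2,
          centers[i, ], `+`)))
  list(X = X, truth = rep(seq_len(nrow(centers)), each = n_each))
}

test_that("linkage basics: identical points merge first, n-1 merges", {
  X <- rbind(c(0, 0), c(5, 5), c(0, 0), c(9, 1))
  d <- distance_matrix(X)
  t1 <- ahc_linkage(d)
  expect_equal(t1$height[1], 0)                      # duplicates first
  expect_setequal(t1$merge[1, ], c(-1, -3))
  t2 <- ahc_linkage(distance_matrix(X[1:3, ]))
  expect_equal(nrow(t2$merge), 2)                    # n - 1 merges
  expect_true(all(diff(t1$height) >= -1e-12))        # non-decreasing heights
})

test_that("ahc_linkage validates the matrix", {
  d <- distance_matrix(matrix(rnorm(10), 5))
  bad <- d; bad[1, 2] <- bad[1, 2] + 1
  expect_error(ahc_linkage(bad), "symmetric")
  bad2 <- d; diag(bad2) <- 1
  expect_error(ahc_linkage(bad2), "zero diagonal")
  expect_error(ahc_linkage(d, "centroid"), "unknown linkage")
})

test_that("average-linkage cut agrees with the brute-force agglomeration", {
  b <- make_blobs(rbind(c(0, 0), c(4, 0), c(0, 4)), 4, sd = 0.2, seed = 21)
  d <- distance_matrix(b$X)
  ids <- cut_tree(ahc_linkage(d, "average"), 3)
  oracle <- naive_average_linkage_cut(d, 3)
  expect_true(same_partition(ids, oracle))
  expect_true(same_partition(ids, b$truth))
  # and on a structureless cloud the two implementations still agree
  set.seed(22)
  d2 <- distance_matrix(matrix(rnorm(24), 12))
  for (k in c(2, 3, 5))
    expect_true(same_partition(cut_tree(ahc_linkage(d2), k),
                               naive_average_linkage_cut(d2, k)))
})

test_that("cut_tree bounds and hierarchy nesting", {
  set.seed(23)
  d <- distance_matrix(matrix(rnorm(30), 15))
  tr <- ahc_linkage(d)
  expect_equal(length(unique(cut_tree(tr, 1))), 1)
  expect_equal(length(unique(cut_tree(tr, 15))), 15)
  expect_error(cut_tree(tr, 0), "out of range")
  expect_error(cut_tree(tr, 16), "out of range")
  for (k in 2:14) {
    fine <- cut_tree(tr, k + 1); coarse <- cut_tree(tr, k)
    # each fine cluster sits inside exactly one coarse cluster
    expect_true(all(rowSums(table(fine, coarse) > 0) == 1))
  }
})

test_that("semantic labels follow the RMS ordering with id tie-breaks", {
  mk <- function(a) as_clip(rep(a, 1000), 1000)
  clips <- list(mk(0.5), mk(0.5), mk(0.2), mk(0.2), mk(0.01), mk(0.01))
  ids <- c(1L, 1L, 2L, 2L, 3L, 3L)
  asg <- assign_semantics(ids, clips)
  expect_equal(asg$labels,
               c("snoring", "snoring", "normal", "normal",
                 "uncertain", "uncertain"))
  # permuting the cluster ids leaves the labels unchanged
  perm <- c(3L, 3L, 1L, 1L, 2L, 2L)
  expect_equal(assign_semantics(perm, clips)$labels, asg$labels)
  # all-equal RMS: id order decides (1 -> snoring, 2 -> normal, 3 -> uncertain)
  eq <- assign_semantics(c(1L, 2L, 3L), list(mk(0.3), mk(0.3), mk(0.3)))
  expect_equal(eq$labels, c("snoring", "normal", "uncertain"))
  expect_error(assign_semantics(c(1L, 2L), list(mk(1), mk(1))), "3 clusters")
})
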