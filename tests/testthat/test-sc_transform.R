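test_that("log transform maps w to log10(1+w), keeping zeros and order", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 99
  m[1, 3] <- m[3, 1] <- 1e5 - 1
  sc <- sc_log_transform(connectome(m, "SC_RAW"))
  expect_equal(sc$matrix[1, 2], 2)          # log10(100)
  expect_equal(sc$matrix[1, 3], 5)          # printed SC range tops out ~5
  expect_equal(sc$matrix[2, 3], 0)          # zeros stay zero
  # monotone in the weight
  w <- sort(stats::runif(50, 0, 1000))
  expect_true(all(diff(log10(1 + w)) > 0))
  expect_error(sc_log_transform(rand_sym_fc(3)), "SC_RAW")
})

test_that("common edge mask is the intersection of nonzero patterns", {
  sc1 <- edge_sc(3, list(c(1, 2), c(2, 3), c(1, 3)))
  sc2 <- edge_sc(3, list(c(1, 2), c(2, 3)))
  mk <- common_edge_mask(list(sc1, sc2))
  expect_equal(mk$count, 2)
  expect_equal(mk$pairs, cbind(i = c(1L, 2L), j = c(2L, 3L)))

  # single SC: mask equals its own nonzero upper triangle
  mk1 <- common_edge_mask(list(sc1))
  expect_equal(mk1$count, 3)

  # disjoint edge sets intersect to nothing
  mk0 <- common_edge_mask(list(edge_sc(4, list(c(1, 2))),
                               edge_sc(4, list(c(3, 4)))))
  expect_equal(mk0$count, 0)
})

test_that("common edge mask shrinks monotonically as subjects are added", {
  scs <- lapply(1:6, function(s) rand_sparse_sc(20, 0.4, seed = s))
  counts <- vapply(1:6, function(k) common_edge_mask(scs[1:k])$count,
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("structural correlation matches hand Pearson computations", {
  sc <- connectome(matrix(c(0, 2, 1, 2, 0, 1, 1, 1, 0), 3, 3), "SC_RAW")
  mk <- common_edge_mask(list(sc))
  cc <- structural_correlation(sc, mk)
  # rows (0,2,1) vs (2,0,1) are perfectly anti-correlated
  expect_equal(cc$matrix[1, 2], -1)
  expect_identical(cc$modality, "SC_CORR")
  expect_equal(cc$matrix, t(cc$matrix))
  expect_true(all(abs(cc$matrix) <= 1))
  expect_equal(diag(cc$matrix), c(0, 0, 0), ignore_attr = TRUE)

  # two nodes with identical structural rows correlate at +1
  m <- matrix(0, 4, 4)
  m[1, 3] <- m[2, 3] <- 2; m[1, 4] <- m[2, 4] <- 5; m[1, 2] <- 1
  m <- m + t(m) - diag(diag(m))
  sc2 <- connectome(m, "SC_RAW")
  cc2 <- structural_correlation(sc2, common_edge_mask(list(sc2)),
                                exclude_pair_entries = TRUE)
  expect_equal(cc2$matrix[1, 2], 1)
})

test_that("structural correlation commutes with node permutation", {
  sc <- rand_sparse_sc(12, 0.5, seed = 3)
  mk <- common_edge_mask(list(sc))
  cc <- structural_correlation(sc, mk)
  perm <- withr::with_seed(1, sample(12))
  scp <- connectome(sc$matrix[perm, perm], "SC_RAW",
                    node_labels = sc$node_labels[perm])
  ccp <- structural_correlation(scp, common_edge_mask(list(scp)))
  expect_equal(ccp$matrix, cc$matrix[perm, perm], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("masked pairs with a degenerate row profile are a hard error", {
  # under the matching-index convention the remaining row of a 3-node line
  # graph is a single value: correlation undefined
  sc <- edge_sc(3, list(c(1, 2), c(2, 3)))
  mk <- common_edge_mask(list(sc))
  expect_error(structural_correlation(sc, mk, exclude_pair_entries = TRUE),
               "constant")
})
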