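test_that("generator is deterministic and matches the design dimensions", {
  spec <- synthetic_spec()
  p1 <- suppressWarnings(generate_hybrid_population(spec, seed = 5))
  p2 <- suppressWarnings(generate_hybrid_population(spec, seed = 5))
  expect_identical(p1$hybrid$X, p2$hybrid$X)
  expect_identical(p1$truth$weights, p2$truth$weights)
  expect_equal(nrow(p1$hybrid$X), 80)  # 8 conditions x 10 subjects
  expect_equal(length(unique(p1$hybrid$condition)), 8)
  expect_equal(anyDuplicated(p1$hybrid$subject_id), 0)
  p3 <- suppressWarnings(generate_hybrid_population(spec, seed = 6))
  expect_false(identical(p1$hybrid$X, p3$hybrid$X))
})

test_that("noiseless cohorts are exactly low rank", {
  spec <- small_spec(seed = 3, noise_rel = 0, trait_scale = 0.02,
                     sensitive_shift = 1)
  pop <- generate_hybrid_population(spec)
  sv <- svd(sweep(pop$hybrid$X, 2, colMeans(pop$hybrid$X)))$d
  expect_lt(sv[4] / sv[1], 1e-10)           # rank <= K = 3
  expect_lte(pca_denoise(pop$hybrid$X, 0.90)$k, 3)
})

test_that("planted weights honor the condition-mean contract", {
  spec <- synthetic_spec()
  pop <- suppressWarnings(generate_hybrid_population(spec, seed = 9))
  A <- pop$truth$weights
  mu <- pop$truth$cond_means
  for (k in 1:2) {  # sensitive traits
    emp <- tapply(A[, k], pop$truth$condition, mean)[colnames(mu)]
    expect_true(all(abs(emp - mu[k, ]) <=
                      3 * spec$weight_sd / sqrt(spec$n_subjects_per_condition)))
  }
})

test_that("oversized trait scale triggers the clipping warning", {
  expect_warning(generate_hybrid_population(small_spec(seed = 1,
                                                       trait_scale = 0.6)),
                 "clipping")
})

test_that("raw cohorts share the core topology and the mask recovers it", {
  spec <- small_spec(seed = 7, p_extra = 0)
  coh <- suppressWarnings(generate_raw_connectomes(spec))
  mk <- common_edge_mask(coh$scs)
  expect_equal(mk$count, coh$mask$count)
  expect_identical(mk$matrix, coh$mask$matrix)
  # with subject-specific extra edges the intersection still equals the core
  spec2 <- small_spec(seed = 7, p_extra = 0.05)
  coh2 <- suppressWarnings(generate_raw_connectomes(spec2))
  expect_identical(common_edge_mask(coh2$scs)$matrix, coh2$mask$matrix)
  # FC matrices carry the hybrid FC block
  idx <- coh$truth$idx
  pop <- suppressWarnings(generate_hybrid_population(spec))
  expect_equal(coh$fcs[[3]]$matrix[idx$fc_pairs],
               pop$hybrid$X[3, seq_len(idx$n_fc)])
})

test_that("cohorts written to disk round-trip through the manifest", {
  d <- file.path(tempdir(), "synthcohort")
  spec <- small_spec(seed = 2, n_nodes = 16, n_subjects_per_condition = 2)
  coh <- suppressWarnings(generate_raw_connectomes(spec, dir = d))
  man <- read_cohort_manifest(file.path(d, "manifest.csv"))
  expect_equal(nrow(man), length(coh$fcs))
  fc <- read_connectome(man$fc_path[1], "FC")
  expect_equal(fc$matrix, coh$fcs[[1]]$matrix, tolerance = 1e-12)
  part <- read_node_partition(file.path(d, "partition.csv"),
                              node_labels = fc$node_labels)
  expect_equal(length(part), 16)
  unlink(d, recursive = TRUE)
})

test_that("recovery evaluation: identity, sign invariance, and a random baseline", {
  pop <- suppressWarnings(generate_hybrid_population(small_spec(seed = 11)))
  truth <- pop$truth
  as_traits <- function(T_mat, W) lapply(seq_len(nrow(T_mat)), function(k)
    structure(list(trait = T_mat[k, ], weights = W[, k],
                   weight_n = rep(1L, nrow(W)), frequency = 1,
                   members = data.frame()), class = "robust_trait"))
  perfect <- evaluate_recovery(truth, as_traits(truth$traits, truth$weights))
  expect_equal(perfect$trait_r, rep(1, 3), tolerance = 1e-9)
  expect_equal(perfect$weight_r, rep(1, 3), tolerance = 1e-9)
  flipped <- evaluate_recovery(truth, as_traits(-truth$traits, -truth$weights))
  expect_equal(flipped$trait_r, rep(1, 3), tolerance = 1e-9)
  L <- ncol(truth$traits)
  rand <- withr::with_seed(8, matrix(rnorm(3 * L), 3, L))
  base <- evaluate_recovery(truth, as_traits(rand, truth$weights))
  expect_lt(mean(base$trait_r), 0.2)
})
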