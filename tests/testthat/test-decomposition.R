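test_that("PCA keeps exactly the rank of a noiseless low-rank matrix", {
  X <- withr::with_seed(1, {
    tcrossprod(matrix(rnorm(10 * 2), 10, 2), matrix(rnorm(50 * 2), 50, 2))
  })
  p <- pca_denoise(X, 0.90)
  expect_equal(p$k, 2L)
  expect_lt(max(abs(p$X_hat - X)), 1e-10)

  # fraction 1.0 reproduces the input
  Y <- withr::with_seed(2, matrix(rnorm(8 * 20), 8, 20))
  expect_equal(pca_denoise(Y, 1.0)$X_hat, Y, tolerance = 1e-10)
  expect_error(pca_denoise(Y, 1.2), "variance_fraction")
})

test_that("PCA at 90% on planted 5-trait data retains between 5 and 10 components", {
  for (s in 1:3) {
    pop <- suppressWarnings(generate_hybrid_population(synthetic_spec(seed = s)))
    k <- pca_denoise(pop$hybrid$X, 0.90)$k
    expect_gte(k, 5); expect_lte(k, 10)
  }
})

test_that("run cohorts have distinct subjects, exact per-condition counts, and are seeded", {
  subj <- rep(sprintf("s%03d", 1:100), each = 8)
  cond <- rep(paste0("c", 1:8), times = 100)
  rows <- sample_run_cohort(subj, cond, 10, seed = 5)
  expect_length(rows, 80)
  expect_equal(anyDuplicated(subj[rows]), 0)
  expect_true(all(table(cond[rows]) == 10))
  expect_identical(rows, sample_run_cohort(subj, cond, 10, seed = 5))
  expect_false(identical(rows, sample_run_cohort(subj, cond, 10, seed = 6)))

  # bijective case: 8 subjects, one condition each, must find the matching
  rows2 <- sample_run_cohort(paste0("s", 1:8), paste0("c", 1:8), 1, seed = 1)
  expect_equal(sort(rows2), 1:8)
  expect_error(sample_run_cohort(c(paste0("s", 1:7), "s1"), paste0("c", 1:8),
                                 1, 1),
               "distinct subjects")
})

test_that("FastICA recovers planted leptokurtic sources from a noiseless mixture", {
  L <- 1500; M <- 3
  S <- withr::with_seed(11, {
    S <- matrix(0, M, L)
    for (k in 1:M) {
      nz <- sample(L, 100)
      S[k, nz] <- rnorm(100, 0, 1)
    }
    S
  })
  A <- withr::with_seed(12, matrix(rnorm(30 * M), 30, M))
  X <- A %*% S
  run <- run_ica(X, M, seed = 99)
  expect_true(run$converged)
  r <- abs(stats::cor(t(run$S), t(S)))
  # each planted source matched by some component up to sign/permutation
  expect_true(all(apply(r, 2, max) > 0.99))
  # mixing weights recovered for the matched components
  for (k in 1:M) {
    j <- which.max(r[, k])
    expect_gt(abs(stats::cor(run$A[, j], A[, k])), 0.99)
  }
  # determinism: same seed, identical result
  run2 <- run_ica(X, M, seed = 99)
  expect_identical(run$S, run2$S)
  expect_identical(run$A, run2$A)
  expect_error(run_ica(X, 31, seed = 1), "rank")
})

test_that("ICA components are unit norm and reconstruct the centered data", {
  pop <- suppressWarnings(generate_hybrid_population(small_spec(seed = 2)))
  Xh <- pca_denoise(pop$hybrid$X, 0.9)$X_hat
  run <- run_ica(Xh, 3, seed = 4)
  expect_equal(unname(rowSums(run$S^2)), rep(1, 3), tolerance = 1e-9)
  Xc <- sweep(Xh, 1, rowMeans(Xh))
  expect_lt(max(abs(run$A %*% run$S - Xc)) / max(abs(Xc)), 0.35)
})

test_that("clustering finds exactly the recurrent component among noise", {
  L <- 400; n_runs <- 10; M <- 4
  common <- withr::with_seed(1, rnorm(L)); common <- common / sqrt(sum(common^2))
  runs <- lapply(1:n_runs, function(r) withr::with_seed(100 + r, {
    S <- matrix(rnorm((M - 1) * L), M - 1, L)
    S <- S / sqrt(rowSums(S^2))
    sgn <- sample(c(-1, 1), 1)
    S <- rbind(sgn * common, S)[sample(M), ]
    structure(list(S = S, A = matrix(rnorm(20 * M), 20, M), rows = 1:20,
                   converged = TRUE, run_id = r, seed = r),
              class = "ica_run")
  }))
  tr <- cluster_robust_traits(runs, r_thresh = 0.5, freq_thresh = 0.5)
  expect_length(tr, 1)
  expect_equal(tr[[1]]$frequency, 1.0)
  expect_gt(abs(stats::cor(tr[[1]]$trait, common)), 0.999)
  expect_equal(nrow(tr[[1]]$members), n_runs)

  # identical runs: every component clusters at frequency 1
  same <- lapply(1:5, function(r) {
    x <- runs[[1]]; x$run_id <- r; x
  })
  tr2 <- cluster_robust_traits(same, 0.5, 0.5)
  expect_length(tr2, M)
  expect_true(all(vapply(tr2, function(t) t$frequency, numeric(1)) == 1))

  # a single run admits no robustness definition
  expect_warning(out <- cluster_robust_traits(runs[1], 0.5, 0.5), "2 converged")
  expect_length(out, 0)
})

test_that("robust trait equals the normalized mean of its sign-aligned members", {
  pop <- suppressWarnings(generate_hybrid_population(small_spec(seed = 6)))
  dec <- suppressMessages(
    decompose_hybrid(pop$hybrid, decomposition_config(n_runs = 6, seed = 3)))
  for (t in dec$traits) {
    expect_gte(t$frequency, 0.5)
    expect_true(all(abs(t$members$r) >= 0.5))
    expect_equal(sqrt(sum(t$trait^2)), 1, tolerance = 1e-9)
  }
})

test_that("number of robust traits is monotone non-increasing in r_thresh", {
  pop <- suppressWarnings(generate_hybrid_population(small_spec(seed = 8)))
  Xh <- pca_denoise(pop$hybrid$X, 0.9)$X_hat
  runs <- lapply(1:8, function(r) run_ica(Xh, 3, seed = r, run_id = r))
  freqs <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th)
    length(cluster_robust_traits(runs, th, 0.5)), integer(1))
  expect_true(all(diff(freqs) <= 0))
})

test_that("model-order selection maximizes task-sensitive robust traits", {
  spec <- small_spec(seed = 10, k_traits = 3, k_sensitive = 2, n_nodes = 36,
                     n_subjects_per_condition = 8)
  pop <- suppressWarnings(generate_hybrid_population(spec))
  cfg <- decomposition_config(n_runs = 5, seed = 2)
  sel <- suppressMessages(select_model_order(pop$hybrid, 2:6, cfg,
                                             icc_threshold = 0.5))
  best <- sel$diagnostics[sel$diagnostics$M == sel$M_star, ]
  expect_equal(best$n_sensitive, 2)
  expect_equal(max(sel$diagnostics$n_sensitive), 2)

  sel4 <- suppressMessages(select_model_order(pop$hybrid, 4, cfg))
  expect_equal(sel4$M_star, 4)
  expect_equal(nrow(sel4$diagnostics), 1)
  expect_error(select_model_order(pop$hybrid, integer(0), cfg), "empty")
})

test_that("pure-noise data yields no sensitive trait and the smallest M", {
  idx <- edge_index(12)
  X <- withr::with_seed(3, matrix(runif(40 * idx$n_fc, -0.5, 0.5), 40))
  h <- hybrid_dataset(X, sprintf("s%02d", 1:40), rep(paste0("c", 1:4), 10), idx)
  w <- testthat::capture_warnings(sel <- suppressMessages(
    select_model_order(h, c(3, 5), decomposition_config(n_runs = 4, seed = 1),
                       icc_threshold = 0.5)))
  expect_true(any(grepl("no candidate", w)))
  expect_equal(sel$M_star, 3)
})

test_that("decomposition is deterministic given the master seed", {
  pop <- suppressWarnings(generate_hybrid_population(small_spec(seed = 12)))
  cfg <- decomposition_config(n_runs = 5, seed = 21)
  d1 <- suppressMessages(decompose_hybrid(pop$hybrid, cfg))
  d2 <- suppressMessages(decompose_hybrid(pop$hybrid, cfg))
  expect_identical(lapply(d1$traits, function(t) t$trait),
                   lapply(d2$traits, function(t) t$trait))
  expect_identical(lapply(d1$traits, function(t) t$weights),
                   lapply(d2$traits, function(t) t$weights))
})
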