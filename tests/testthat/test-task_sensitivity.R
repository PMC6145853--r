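test_that("hand-computed one-way ANOVA cases reproduce exactly", {
  # perfect separation: within variance zero
  r1 <- icc_oneway(c(1, 1, 3, 3), c("a", "a", "b", "b"))
  expect_equal(r1$msw, 0)
  expect_equal(r1$msb, 4)
  expect_equal(r1$icc, 1)
  # identical groups: no between variance
  r2 <- icc_oneway(c(1, 2, 1, 2), c("a", "a", "b", "b"))
  expect_equal(r2$msb, 0)
  expect_equal(r2$msw, 0.5)
  expect_equal(r2$icc, -1)
})

test_that("icc matches the aov mean squares on random unbalanced groups", {
  for (s in 1:300) {
    dat <- withr::with_seed(1000 + s, {
      ng <- sample(2:6, 1)
      sizes <- sample(2:8, ng, replace = TRUE)
      g <- rep(letters[1:ng], times = sizes)
      list(x = rnorm(length(g), mean = rep(rnorm(ng, sd = 1.5), times = sizes)),
           g = g)
    })
    mine <- icc_oneway(dat$x, dat$g)
    ms <- summary(stats::aov(dat$x ~ factor(dat$g)))[[1]][["Mean Sq"]]
    N <- length(dat$x); ki <- table(dat$g); gN <- length(ki)
    k0 <- (N - sum(ki^2) / N) / (gN - 1)
    oracle <- (ms[1] - ms[2]) / (ms[1] + (k0 - 1) * ms[2])
    expect_equal(mine$icc, oracle, tolerance = 1e-10)
    expect_equal(mine$msb, ms[1], tolerance = 1e-10)
    expect_equal(mine$msw, ms[2], tolerance = 1e-10)
  }
})

test_that("icc is invariant to shifting and positive rescaling of the weights", {
  x <- withr::with_seed(5, rnorm(40, rep(c(0, 1, 0, 2), each = 10)))
  g <- rep(letters[1:4], each = 10)
  base <- icc_oneway(x, g)$icc
  expect_equal(icc_oneway(x + 100, g)$icc, base, tolerance = 1e-12)
  expect_equal(icc_oneway(3.7 * x, g)$icc, base, tolerance = 1e-12)
})

test_that("null ICC over many simulated cohorts is centered near zero", {
  iccs <- vapply(1:1000, function(s) withr::with_seed(2000 + s, {
    icc_oneway(rnorm(80), rep(paste0("c", 1:8), each = 10))$icc
  }), numeric(1))
  expect_lt(abs(mean(iccs)), 0.02)
})

test_that("icc input validation: missing weights, tiny groups, constant data", {
  expect_error(icc_oneway(1:4, rep("a", 4)), "2 groups")
  expect_error(icc_oneway(c(1, 2, 3), c("a", "a", "b")), "2 non-missing")
  expect_error(icc_oneway(rep(1, 8), rep(c("a", "b"), 4)), "identical")
  # missing values are dropped with their labels
  x <- c(1, 2, NA, 1.5, 2.5, 3)
  g <- c("a", "a", "a", "b", "b", "b")
  expect_equal(icc_oneway(x, g)$group_sizes, c(2L, 3L))
})

test_that("classification separates planted sensitive from insensitive traits", {
  wins <- 0
  for (s in 1:100) {
    pop <- suppressWarnings(generate_hybrid_population(
      small_spec(seed = 300 + s, k_traits = 3, k_sensitive = 1)))
    A <- pop$truth$weights
    icc_sens <- icc_oneway(A[, 1], pop$truth$condition)$icc
    icc_ins <- max(icc_oneway(A[, 2], pop$truth$condition)$icc,
                   icc_oneway(A[, 3], pop$truth$condition)$icc)
    wins <- wins + (icc_sens > icc_ins)
  }
  expect_gte(wins, 95)
})

test_that("classify_task_sensitive sorts by ICC and honors the threshold", {
  pop <- suppressWarnings(generate_hybrid_population(small_spec(seed = 44)))
  dec <- suppressMessages(
    decompose_hybrid(pop$hybrid, decomposition_config(n_runs = 5, seed = 9)))
  rep1 <- classify_task_sensitive(dec, icc_threshold = 0.5)
  expect_true(!is.unsorted(rev(rep1$icc)))
  rep0 <- classify_task_sensitive(dec$traits, dec$condition, icc_threshold = 0)
  expect_true(all(rep0$task_sensitive[rep0$icc >= 0]))
  one <- classify_task_sensitive(dec$traits[1], dec$condition)
  expect_equal(nrow(one), 1)
})
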