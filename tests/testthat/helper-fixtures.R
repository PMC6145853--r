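# Fixtures are generated in code; nothing is read from disk except what a
# test itself writes to tempdir().

rand_sym_fc <- function(n, seed = 1) {
  m <- withr::with_seed(seed, matrix(stats::runif(n * n, -1, 1), n, n))
  m <- (m + t(m)) / 2
  diag(m) <- 0
  connectome(m, "FC")
}

rand_sparse_sc <- function(n, density = 0.2, seed = 1, subject_id = NA,
                           condition = NA) {
  m <- withr::with_seed(seed, {
    m <- matrix(0, n, n)
    ut <- which(upper.tri(m))
    on <- ut[stats::runif(length(ut)) < density]
    m[on] <- stats::rlnorm(length(on), log(30), 1)
    m
  })
  m <- m + t(m)
  connectome(m, "SC_RAW", subject_id = subject_id, condition = condition)
}

# connectome from an explicit edge list on n nodes (unit weights)
edge_sc <- function(n, edges) {
  m <- matrix(0, n, n)
  for (e in edges) m[e[1], e[2]] <- m[e[2], e[1]] <- 1
  connectome(m, "SC_RAW")
}

small_spec <- function(seed = 1, ...) {
  args <- list(n_nodes = 32, n_conditions = 4, n_subjects_per_condition = 5,
               k_traits = 3, k_sensitive = 1, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synthetic_spec, args)
}
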