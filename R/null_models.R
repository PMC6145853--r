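#' Degree-preserving randomization of a structural connectome
#'
#' Double-edge-swap null model: repeatedly draw two edges (a,b) and (c,d)
#' with four distinct endpoints and rewire them to (a,d) and (c,b) when
#' neither target edge exists. Each accepted swap preserves the graph's
#' size, density, and degree sequence exactly; weights travel with their
#' original edge, so the weight multiset is conserved too. Randomization
#' destroys everything else about the topology (clustering, communities),
#' which is exactly what the null is for: testing whether joint FC-SC
#' structure survives when the structural architecture is scrambled.
#'
#' @param sc `SC_RAW` [connectome] with at least 2 edges.
#' @param n_swaps number of *accepted* swaps to perform.
#' @param seed integer seed.
#' @param attempt_cap maximum candidate draws before giving up (default
#'   `100 * n_swaps`); constrained graphs (e.g. a triangle or a complete
#'   graph) may admit no legal swap.
#' @return object of class `swap_null`: `connectome` (randomized),
#'   `requested`, `accepted`, `attempts`, `seed`, `capped` (TRUE if the
#'   attempt cap was hit), `invariants` (n, edge count, sorted degree
#'   sequence before/after).
#' @export
degree_preserving_randomize <- function(sc, n_swaps, seed,
                                        attempt_cap = 100 * n_swaps) {
  stopifnot(inherits(sc, "connectome"), n_swaps >= 0)
  m <- sc$matrix
  n <- nrow(m)
  pr <- upper_pairs(n)
  on <- m[pr] != 0
  ei <- pr[on, 1]; ej <- pr[on, 2]
  w <- m[pr][on]
  nE <- length(ei)
  if (nE < 2) stop("need at least 2 edges to swap")
  deg_before <- tabulate(c(ei, ej), n)
  A <- matrix(FALSE, n, n)
  A[cbind(ei, ej)] <- TRUE; A[cbind(ej, ei)] <- TRUE
  accepted <- 0L; attempts <- 0L
  with_seed(seed, {
    while (accepted < n_swaps && attempts < attempt_cap) {
      attempts <- attempts + 1L
      e1 <- sample.int(nE, 1L); e2 <- sample.int(nE, 1L)
      if (e1 == e2) next
      a <- ei[e1]; b <- ej[e1]; c_ <- ei[e2]; d <- ej[e2]
      # random orientation of the second edge for uniform rewiring
      if (stats::runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
      if (a == c_ || a == d || b == c_ || b == d) next
      if (A[a, d] || A[c_, b]) next
      A[a, b] <- A[b, a] <- FALSE
      A[c_, d] <- A[d, c_] <- FALSE
      A[a, d] <- A[d, a] <- TRUE
      A[c_, b] <- A[b, c_] <- TRUE
      ei[e1] <- min(a, d); ej[e1] <- max(a, d)
      ei[e2] <- min(c_, b); ej[e2] <- max(c_, b)
      accepted <- accepted + 1L
    }
  })
  out <- matrix(0, n, n)
  out[cbind(ei, ej)] <- w; out[cbind(ej, ei)] <- w
  deg_after <- tabulate(c(ei, ej), n)
  rand <- connectome(out, "SC_RAW", node_labels = sc$node_labels,
                     subject_id = sc$subject_id, condition = sc$condition)
  capped <- accepted < n_swaps
  if (capped)
    warning("attempt cap reached: ", accepted, " of ", n_swaps,
            " swaps accepted (graph too constrained)")
  structure(list(connectome = rand, requested = as.integer(n_swaps),
                 accepted = accepted, attempts = attempts,
                 seed = as.integer(seed), capped = capped,
                 invariants = list(n = n, n_edges = nE,
                                   degree_before = sort(deg_before),
                                   degree_after = sort(deg_after))),
            class = "swap_null")
}

#' @export
print.swap_null <- function(x, ...) {
  cat(sprintf("<swap_null> %d/%d swaps accepted in %d attempts (n=%d, |E|=%d)%s\n",
              x$accepted, x$requested, x$attempts, x$invariants$n,
              x$invariants$n_edges, if (x$capped) " [capped]" else ""))
  invisible(x)
}

#' Dissimilarity of the randomized connectome vs. number of swaps
#'
#' For each swap count in `swap_grid`, randomizes the connectome `n_reps`
#' times (fresh seeds) and reports the mean topological dissimilarity,
#' 1 - Jaccard index of the edge sets, plus the mean weight dissimilarity,
#' 1 - Pearson r between the vectorized weights on the union of supports.
#' The curve is non-decreasing in expectation and is how one picks the
#' number of swaps giving maximal dissimilarity at minimal cost.
#'
#' @param sc `SC_RAW` [connectome].
#' @param swap_grid increasing vector of swap counts.
#' @param n_reps randomizations per grid point.
#' @param seed master seed.
#' @return data.frame: swaps, mean_jaccard_dissimilarity,
#'   mean_weight_dissimilarity, mean_accepted.
#' @export
dissimilarity_curve <- function(sc, swap_grid, n_reps = 20, seed = 1L) {
  stopifnot(all(diff(swap_grid) >= 0))
  pr <- upper_pairs(nrow(sc$matrix))
  w0 <- sc$matrix[pr]
  e0 <- w0 != 0
  seeds <- spawn_seeds(seed, length(swap_grid) * n_reps)
  k <- 0L
  rows <- lapply(seq_along(swap_grid), function(gi) {
    s <- swap_grid[gi]
    jac <- num <- acc <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      k <<- k + 1L
      rnd <- suppressWarnings(
        degree_preserving_randomize(sc, s, seeds[(gi - 1L) * n_reps + r]))
      w1 <- rnd$connectome$matrix[pr]
      e1 <- w1 != 0
      inter <- sum(e0 & e1); uni <- sum(e0 | e1)
      jac[r] <- 1 - inter / uni
      supp <- e0 | e1
      num[r] <- if (stats::sd(w0[supp]) > 0 && stats::sd(w1[supp]) > 0)
        1 - stats::cor(w0[supp], w1[supp]) else 0
      acc[r] <- rnd$accepted
    }
    data.frame(swaps = s,
               mean_jaccard_dissimilarity = mean(jac),
               mean_weight_dissimilarity = mean(num),
               mean_accepted = mean(acc))
  })
  do.call(rbind, rows)
}
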