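#' Decomposition configuration
#'
#' Bundles every tunable of the multi-run ICA decomposition. The defaults
#' are the reference settings of the method: PCA retaining 90% variance,
#' 10 independent components, 100 FastICA runs over bootstrap cohorts of
#' 10 subjects per condition, and robustness thresholds of |r| >= 0.5
#' appearing in >= 50% of runs.
#'
#' @param n_components requested number of independent components M. When
#'   the PCA-reconstructed matrix (or a run's subset) has lower rank, M is
#'   clamped to that rank.
#' @param variance_fraction cumulative explained-variance cutoff for PCA.
#' @param n_runs number of FastICA runs.
#' @param r_thresh minimum |Pearson r| for two components in different runs
#'   to count as the same trait.
#' @param freq_thresh minimum fraction of runs a trait must appear in.
#' @param n_per_condition bootstrap cohort size per condition; `NA` uses
#'   every profile in every run.
#' @param fun ICA contrast function (`"tanh"` or `"cube"`).
#' @param max_iter,tol FastICA fixed-point iteration controls.
#' @param seed master seed; per-run cohort and initialization seeds are
#'   spawned from it deterministically.
#' @return a list of class `decomposition_config`.
#' @export
decomposition_config <- function(n_components = 10, variance_fraction = 0.90,
                                 n_runs = 100, r_thresh = 0.5,
                                 freq_thresh = 0.50, n_per_condition = 10,
                                 fun = c("tanh", "cube"), max_iter = 500,
                                 tol = 1e-6, seed = 1L) {
  fun <- match.arg(fun)
  stopifnot(n_components >= 2, variance_fraction > 0, variance_fraction <= 1,
            n_runs >= 1, r_thresh > 0, r_thresh <= 1,
            freq_thresh > 0, freq_thresh <= 1)
  structure(list(n_components = n_components,
                 variance_fraction = variance_fraction, n_runs = n_runs,
                 r_thresh = r_thresh, freq_thresh = freq_thresh,
                 n_per_condition = n_per_condition, fun = fun,
                 max_iter = max_iter, tol = tol, seed = as.integer(seed)),
            class = "decomposition_config")
}

#' PCA denoising of the hybrid matrix
#'
#' Column-centers the profiles-by-edges matrix, keeps the smallest number
#' of leading principal components whose cumulative explained variance
#' reaches `variance_fraction`, and returns the rank-k reconstruction with
#' the column means added back, so the denoised matrix keeps the original
#' scale. ICA is then run on this reconstructed matrix.
#'
#' @param X numeric matrix (profiles x edges) or a `hybrid_dataset`.
#' @param variance_fraction cumulative explained-variance cutoff in (0, 1].
#' @return list: `X_hat` (reconstruction), `k` (components retained),
#'   `explained` (cumulative explained-variance curve).
#' @export
pca_denoise <- function(X, variance_fraction = 0.90) {
  if (inherits(X, "hybrid_dataset")) X <- X$X
  stopifnot(is.matrix(X), nrow(X) >= 2)
  if (variance_fraction > 1 || variance_fraction <= 0)
    stop("variance_fraction must be in (0, 1]")
  cm <- colMeans(X)
  Xc <- sweep(X, 2, cm)
  sv <- svd(Xc)
  ev <- sv$d^2
  tot <- sum(ev)
  if (tot == 0) return(list(X_hat = X, k = 0L, explained = numeric(0)))
  cum <- cumsum(ev) / tot
  k <- which(cum >= variance_fraction - 1e-12)[1]
  Xhat <- sv$u[, seq_len(k), drop = FALSE] %*%
    (sv$d[seq_len(k)] * t(sv$v[, seq_len(k), drop = FALSE]))
  Xhat <- sweep(Xhat, 2, cm, `+`)
  list(X_hat = Xhat, k = as.integer(k), explained = cum)
}

#' Sample a bootstrap run cohort
#'
#' Selects `n_per_condition` profiles per condition such that every chosen
#' subject is distinct across the whole sample — the bootstrap draws whole
#' subjects, not repeated measurements. Deterministic given `seed`.
#'
#' @param subject_id,condition character vectors describing the available
#'   profiles (parallel).
#' @param n_per_condition profiles to draw per condition.
#' @param seed integer seed.
#' @param max_retry restarts allowed before declaring the cohort infeasible.
#' @return integer vector of selected row indices.
#' @export
sample_run_cohort <- function(subject_id, condition, n_per_condition, seed,
                              max_retry = 100) {
  stopifnot(length(subject_id) == length(condition))
  conds <- unique(condition)
  need <- n_per_condition * length(conds)
  if (length(unique(subject_id)) < need)
    stop("need ", need, " distinct subjects; only ",
         length(unique(subject_id)), " available")
  with_seed(seed, {
    for (try in seq_len(max_retry)) {
      used <- character(0)
      pick <- integer(0)
      ok <- TRUE
      for (cc in sample(conds)) {
        rows <- which(condition == cc & !(subject_id %in% used))
        # one profile per subject within the condition
        rows <- rows[!duplicated(subject_id[rows])]
        if (length(rows) < n_per_condition) { ok <- FALSE; break }
        sel <- rows[sample.int(length(rows), n_per_condition)]
        pick <- c(pick, sel)
        used <- c(used, subject_id[sel])
      }
      if (ok) return(sort(pick))
    }
  })
  stop("could not sample a cohort with ", n_per_condition,
       " distinct subjects per condition")
}

# FastICA: fixed-point algorithm with symmetric decorrelation.
# X is profiles x edges; each row is treated as one mixed signal observed
# across edges. Returns M unit-norm source vectors over edge space (the
# hybrid traits, rows of S) and the mixing weights A (profiles x M) with
# X_centered ~ A %*% S.
fastica_symm <- function(X, M, seed, fun = "tanh", max_iter = 500, tol = 1e-6,
                         rank_tol = 1e-9) {
  P <- nrow(X); L <- ncol(X)
  rmeans <- rowMeans(X)
  Xc <- X - rmeans
  C <- tcrossprod(Xc) / L
  eg <- eigen(C, symmetric = TRUE)
  pos <- eg$values > rank_tol * max(eg$values, 0)
  rank <- sum(pos)
  if (M > rank)
    stop("requested ", M, " components but data rank is ", rank)
  vals <- eg$values[seq_len(M)]
  vecs <- eg$vectors[, seq_len(M), drop = FALSE]
  K <- t(vecs) / sqrt(vals)           # M x P whitening
  Z <- K %*% Xc                        # M x L, white
  sym_decorr <- function(W) { s <- svd(W); s$u %*% t(s$v) }
  W <- with_seed(seed, matrix(stats::rnorm(M * M), M, M))
  W <- sym_decorr(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    if (fun == "tanh") {
      G <- tanh(WZ)
      gp <- rowMeans(1 - G^2)
    } else {                           # cube (kurtosis) contrast
      G <- WZ^3
      gp <- rowMeans(3 * WZ^2)
    }
    W1 <- sym_decorr(tcrossprod(G, Z) / L - gp * W)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  S <- W %*% Z                         # M x L sources
  A <- vecs %*% (sqrt(vals) * t(W))    # P x M mixing
  # fix the scale ambiguity: unit-norm traits, magnitude carried by weights
  ns <- sqrt(rowSums(S^2))
  S <- S / ns
  A <- A * rep(ns, each = P)
  list(S = S, A = A, converged = converged, n_iter = it)
}

#' Run FastICA once on a (subset of the) denoised hybrid matrix
#'
#' Fixed-point FastICA with symmetric decorrelation and the configured
#' contrast function. Sources live in hybrid-edge space (the candidate
#' traits, unit L2 norm); the mixing matrix holds the per-profile weights.
#'
#' @param X denoised matrix (profiles x edges), already a run subset.
#' @param M number of components; must not exceed the matrix rank.
#' @param seed seed for the random orthogonal initialization.
#' @param rows global profile indices of the subset (bookkeeping for
#'   cross-run weight averaging); defaults to `1:nrow(X)`.
#' @param run_id identifier stored with the result.
#' @param fun,max_iter,tol see [decomposition_config()].
#' @return object of class `ica_run`: `S` (M x L traits), `A` (weights),
#'   `rows`, `converged`, `n_iter`, `run_id`, `seed`.
#' @export
run_ica <- function(X, M, seed, rows = seq_len(nrow(X)), run_id = 1L,
                    fun = "tanh", max_iter = 500, tol = 1e-6) {
  stopifnot(is.matrix(X), length(rows) == nrow(X))
  res <- fastica_symm(X, M, seed, fun = fun, max_iter = max_iter, tol = tol)
  structure(list(S = res$S, A = res$A, rows = rows,
                 converged = res$converged, n_iter = res$n_iter,
                 run_id = run_id, seed = seed),
            class = "ica_run")
}

#' Cluster components across runs into robust traits
#'
#' FastICA is non-deterministic; only components that recur across runs are
#' trusted. Greedy clustering: among unclustered components, seed with the
#' one matched (|Pearson r| >= `r_thresh`) in the most other runs; every run
#' contributes at most its best-matching component; members are sign-flipped
#' to correlate positively with the seed; the robust trait is the member
#' mean (re-normalized) and its weights are, per profile, the mean over the
#' member runs that sampled that profile. Clusters appearing in fewer than
#' `freq_thresh` of the converged runs are discarded.
#'
#' @param runs list of `ica_run` objects (non-converged runs are dropped).
#' @param r_thresh,freq_thresh see [decomposition_config()].
#' @param n_profiles total number of profiles in the cohort (for the weight
#'   vector length); defaults to the max row index seen.
#' @return list of `robust_trait` objects, sorted by frequency (descending).
#'   Each has: `trait` (unit-norm hybrid vector), `weights` (length
#'   `n_profiles`, NA where never sampled), `weight_n` (appearance counts),
#'   `frequency`, `members` (data.frame run/comp/r/sign).
#' @export
cluster_robust_traits <- function(runs, r_thresh = 0.5, freq_thresh = 0.5,
                                  n_profiles = NULL) {
  runs <- Filter(function(r) isTRUE(r$converged), runs)
  if (length(runs) < 2) {
    warning("fewer than 2 converged runs; no robust trait can be defined")
    return(list())
  }
  n_runs <- length(runs)
  if (is.null(n_profiles))
    n_profiles <- max(vapply(runs, function(r) max(r$rows), integer(1)))
  S_all <- do.call(rbind, lapply(runs, function(r) r$S))
  run_of <- rep(seq_along(runs), vapply(runs, function(r) nrow(r$S), integer(1)))
  comp_of <- unlist(lapply(runs, function(r) seq_len(nrow(r$S))))
  R <- stats::cor(t(S_all))
  aR <- abs(R); diag(aR) <- 0
  free <- rep(TRUE, nrow(S_all))
  traits <- list()
  repeat {
    idx_free <- which(free)
    if (length(idx_free) == 0) break
    # matches = number of *other* runs holding a free component above threshold
    n_match <- vapply(idx_free, function(i) {
      hit <- idx_free[aR[i, idx_free] >= r_thresh & run_of[idx_free] != run_of[i]]
      length(unique(run_of[hit]))
    }, integer(1))
    if (max(n_match) == 0) break
    seed_i <- idx_free[which.max(n_match)]
    members <- seed_i
    for (rr in setdiff(seq_len(n_runs), run_of[seed_i])) {
      cand <- idx_free[run_of[idx_free] == rr]
      if (length(cand) == 0) next
      best <- cand[which.max(aR[seed_i, cand])]
      if (aR[seed_i, best] >= r_thresh) members <- c(members, best)
    }
    signs <- sign(R[seed_i, members]); signs[members == seed_i] <- 1
    tr <- colMeans(S_all[members, , drop = FALSE] * signs)
    tr <- tr / sqrt(sum(tr^2))
    w_sum <- numeric(n_profiles); w_cnt <- integer(n_profiles)
    for (m in seq_along(members)) {
      r_obj <- runs[[run_of[members[m]]]]
      w <- signs[m] * r_obj$A[, comp_of[members[m]]]
      w_sum[r_obj$rows] <- w_sum[r_obj$rows] + w
      w_cnt[r_obj$rows] <- w_cnt[r_obj$rows] + 1L
    }
    weights <- ifelse(w_cnt > 0, w_sum / w_cnt, NA_real_)
    traits[[length(traits) + 1]] <- structure(
      list(trait = tr, weights = weights, weight_n = w_cnt,
           frequency = length(members) / n_runs,
           members = data.frame(run = run_of[members], comp = comp_of[members],
                                r = R[seed_i, members], sign = signs)),
      class = "robust_trait")
    free[members] <- FALSE
  }
  traits <- Filter(function(t) t$frequency >= freq_thresh, traits)
  traits[order(vapply(traits, function(t) t$frequency, numeric(1)),
               decreasing = TRUE)]
}

#' @export
print.robust_trait <- function(x, ...) {
  cat(sprintf("<robust_trait> frequency %.2f, %d member run(s)%s\n",
              x$frequency, nrow(x$members),
              if (!is.null(x$icc)) sprintf(", ICC %.3f", x$icc) else ""))
  invisible(x)
}

#' Full multi-run decomposition of a hybrid dataset
#'
#' PCA-denoises the hybrid matrix, then runs FastICA `n_runs` times, each
#' run on a bootstrap cohort of `n_per_condition` distinct subjects per
#' condition (or on all profiles when the cohort is exactly that size /
#' `n_per_condition` is `NA`), and clusters the components into robust
#' traits. The requested model order is clamped to the post-PCA rank.
#'
#' @param h a `hybrid_dataset`.
#' @param config a [decomposition_config()].
#' @return list of class `decomposition`: `traits` (robust traits),
#'   `runs_converged`, `n_runs`, `pca_k`, `M_used`, `config`, plus the
#'   dataset's `condition` / `subject_id` for downstream scoring.
#' @export
decompose_hybrid <- function(h, config = decomposition_config()) {
  stopifnot(inherits(h, "hybrid_dataset"))
  P <- nrow(h$X)
  pca <- pca_denoise(h$X, config$variance_fraction)
  M <- min(config$n_components, pca$k)
  if (M < config$n_components)
    message("model order clamped from ", config$n_components,
            " to post-PCA rank ", M)
  if (M < 2) stop("post-PCA rank < 2; nothing to decompose")
  seeds <- spawn_seeds(config$seed, 2L * config$n_runs)
  npc <- config$n_per_condition
  conds <- unique(h$condition)
  subsample <- !is.na(npc) &&
    length(unique(h$subject_id)) > npc * length(conds)
  runs <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    rows <- if (subsample)
      sample_run_cohort(h$subject_id, h$condition, npc, seeds[2L * r - 1L])
    else seq_len(P)
    res <- tryCatch(
      run_ica(pca$X_hat[rows, , drop = FALSE], M, seeds[2L * r],
              rows = rows, run_id = r, fun = config$fun,
              max_iter = config$max_iter, tol = config$tol),
      error = function(e) NULL)
    if (!is.null(res)) runs[[r]] <- res
  }
  runs <- Filter(Negate(is.null), runs)
  traits <- cluster_robust_traits(runs, config$r_thresh, config$freq_thresh,
                                  n_profiles = P)
  structure(list(traits = traits,
                 runs_converged = sum(vapply(runs, function(r) r$converged,
                                             logical(1))),
                 n_runs = config$n_runs, pca_k = pca$k, M_used = M,
                 config = config, condition = h$condition,
                 subject_id = h$subject_id, idx = h$idx),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> %d robust trait(s) from %d/%d converged runs (PCA k=%d, M=%d)\n",
              length(x$traits), x$runs_converged, x$n_runs, x$pca_k, x$M_used))
  for (t in x$traits) print(t)
  invisible(x)
}

#' Heuristic model-order selection
#'
#' Runs a (typically reduced) decomposition for each candidate number of
#' components and scores it by the number of robust traits whose weight ICC
#' across conditions reaches `icc_threshold`; ties are broken by higher mean
#' ICC of the robust traits, then by smaller M. This mirrors the heuristic
#' of jointly maximizing robustness and task sensitivity.
#'
#' @param h a `hybrid_dataset`.
#' @param M_range integer candidates (each must be >= 2 and at most the
#'   post-PCA rank; larger candidates are clamped, duplicates dropped).
#' @param config base [decomposition_config()] (its `n_components` is
#'   overridden per candidate).
#' @param icc_threshold task-sensitivity cut on ICC.
#' @return list: `M_star`, `diagnostics` (data.frame with one row per
#'   candidate: M, n_robust, n_sensitive, mean_icc, score).
#' @export
select_model_order <- function(h, M_range, config = decomposition_config(),
                               icc_threshold = 0.5) {
  if (length(M_range) == 0) stop("empty M_range")
  rows <- lapply(M_range, function(M) {
    cfg <- config; cfg$n_components <- M
    dec <- decompose_hybrid(h, cfg)
    iccs <- vapply(dec$traits, function(t) {
      tryCatch(icc_oneway(t$weights, h$condition)$icc,
               error = function(e) NA_real_)
    }, numeric(1))
    n_sens <- sum(iccs >= icc_threshold, na.rm = TRUE)
    data.frame(M = M, M_used = dec$M_used, n_robust = length(dec$traits),
               n_sensitive = n_sens,
               mean_icc = if (length(iccs)) mean(iccs, na.rm = TRUE) else NA_real_)
  })
  diag_df <- do.call(rbind, rows)
  diag_df$score <- diag_df$n_sensitive
  ord <- order(-diag_df$score,
               -ifelse(is.finite(diag_df$mean_icc), diag_df$mean_icc, -Inf),
               diag_df$M)
  best <- diag_df[ord[1], ]
  if (best$score == 0)
    warning("no candidate produced a task-sensitive robust trait; ",
            "returning smallest M by tie-break")
  list(M_star = best$M, diagnostics = diag_df)
}
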