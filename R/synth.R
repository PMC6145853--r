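#' Specification of a synthetic hybrid-connectome cohort
#'
#' Describes a cohort emulating the study design the method targets: P =
#' `n_conditions * n_subjects_per_condition` subject-condition profiles
#' (default 8 conditions x 10 subjects = 80), K latent hybrid traits with
#' network-block structure, condition-modulated weights for the
#' task-sensitive traits, i.i.d. edge noise, and a shared sparse structural
#' topology drawn from a stochastic block model over resting-state
#' networks.
#'
#' Trait vectors are built from +/- blocks on within- and between-RSN edge
#' sets, mutually orthogonalized, and scaled to a root-mean-square entry of
#' `trait_scale`. Weights are Normal with sd `weight_sd`; task-sensitive
#' traits get per-condition means spread over `sensitive_shift * weight_sd`
#' (a standardized, per-trait-permuted condition profile), insensitive
#' traits a common zero mean with subject-level sd inflated to
#' `weight_sd * sqrt(1 + sensitive_shift^2)` so that every planted trait
#' carries the same total expression variance (a robust but
#' task-insensitive trait is not a weak trait). The expected ICC of a
#' sensitive trait is then `sensitive_shift^2 / (1 + sensitive_shift^2)`
#' (~0.69 at the default 1.5). Edge noise is Normal with sd
#' `noise_rel * trait_scale`.
#'
#' @param n_nodes number of regions (split into 8 RSN blocks).
#' @param n_conditions,n_subjects_per_condition cohort design.
#' @param k_traits,k_sensitive planted traits and how many are
#'   condition-modulated.
#' @param trait_scale RMS entry magnitude of each planted trait.
#' @param noise_rel edge-noise sd as a fraction of `trait_scale`.
#' @param weight_sd subject-level sd of the planted weights.
#' @param sensitive_shift spread of per-condition weight means, in units of
#'   `weight_sd`.
#' @param block_jitter sd of the dense jitter added to the block pattern
#'   before orthogonalization.
#' @param p_within,p_between core (population-shared) structural edge
#'   probabilities within/between RSN blocks.
#' @param p_extra per-subject probability of a non-core structural edge.
#' @param sc_meanlog,sc_sdlog lognormal parameters of core streamline
#'   weights; `sc_subject_sdlog` is the per-subject multiplicative jitter.
#' @param conditions condition labels.
#' @param seed master seed; the whole cohort is a deterministic function of
#'   the spec.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_nodes = 60, n_conditions = 8,
                           n_subjects_per_condition = 10,
                           k_traits = 5, k_sensitive = 2,
                           trait_scale = 0.05, noise_rel = 0.2,
                           weight_sd = 1, sensitive_shift = 1.5,
                           block_jitter = 0.05,
                           p_within = 0.5, p_between = 0.10, p_extra = 0.03,
                           sc_meanlog = log(30), sc_sdlog = 1,
                           sc_subject_sdlog = 0.25,
                           conditions = c("rest", paste0("task", 1:7)),
                           seed = 1L) {
  stopifnot(n_nodes >= 16, k_sensitive <= k_traits,
            k_traits <= n_conditions * n_subjects_per_condition,
            noise_rel >= 0, length(conditions) >= n_conditions)
  structure(list(n_nodes = n_nodes, n_conditions = n_conditions,
                 n_subjects_per_condition = n_subjects_per_condition,
                 k_traits = k_traits, k_sensitive = k_sensitive,
                 trait_scale = trait_scale, noise_rel = noise_rel,
                 weight_sd = weight_sd, sensitive_shift = sensitive_shift,
                 block_jitter = block_jitter,
                 p_within = p_within, p_between = p_between,
                 p_extra = p_extra, sc_meanlog = sc_meanlog,
                 sc_sdlog = sc_sdlog, sc_subject_sdlog = sc_subject_sdlog,
                 conditions = conditions[seq_len(n_conditions)],
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Contiguous near-equal assignment of nodes to the 8 canonical RSNs.
synth_partition <- function(n_nodes) {
  rsns <- c("VIS", "SM", "DA", "VA", "L", "FP", "DMN", "SUBC")
  sizes <- diff(round(seq(0, n_nodes, length.out = 9)))
  stats::setNames(rep(rsns, sizes), paste0("n", seq_len(n_nodes)))
}

# Shared core structural topology: SBM over RSN blocks, guaranteed connected
# support for every node (each node gets at least one within-block edge).
synth_core_mask <- function(spec, seed) {
  n <- spec$n_nodes
  part <- synth_partition(n)
  grp <- match(part, unique(part))
  pr <- upper_pairs(n)
  same <- grp[pr[, 1]] == grp[pr[, 2]]
  keep <- with_seed(seed, {
    p <- ifelse(same, spec$p_within, spec$p_between)
    stats::runif(nrow(pr)) < p
  })
  m <- matrix(FALSE, n, n)
  m[pr[keep, , drop = FALSE]] <- TRUE
  m <- m | t(m)
  # every node needs a structural neighbour, else its SC row is constant
  iso <- which(rowSums(m) == 0)
  for (i in iso) {
    j <- if (i < n) i + 1L else i - 1L
    m[i, j] <- m[j, i] <- TRUE
  }
  sc <- connectome(1 * m, "SC_RAW", node_labels = names(part))
  common_edge_mask(list(sc))
}

# Block-structured, orthogonalized planted traits (k_traits x L).
synth_traits <- function(spec, idx, seed) {
  n <- spec$n_nodes
  part <- synth_partition(n)
  grp <- match(part, unique(part))
  n_rsn <- max(grp)
  L <- idx$n_fc + idx$n_sc
  pair_block <- function(pairs) cbind(grp[pairs[, 1]], grp[pairs[, 2]])
  fc_b <- pair_block(idx$fc_pairs)
  sc_b <- pair_block(idx$sc_pairs)
  with_seed(seed, {
    T_mat <- matrix(0, spec$k_traits, L)
    for (k in seq_len(spec$k_traits)) {
      # disjoint supports across traits: trait k owns the within-RSN block
      # of its primary network plus one between-RSN block; no edge set is
      # shared between two traits (for k_traits <= n_rsn)
      primary <- ((k - 1) %% n_rsn) + 1
      partner <- ((k - 1 + 3) %% n_rsn) + 1
      v <- numeric(L)
      in_blocks <- function(bm) {
        (bm[, 1] == primary & bm[, 2] == primary) * 1 +
          (pmin(bm[, 1], bm[, 2]) == min(primary, partner) &
             pmax(bm[, 1], bm[, 2]) == max(primary, partner)) * -1
      }
      v[seq_len(idx$n_fc)] <- in_blocks(fc_b)
      if (idx$n_sc > 0)
        v[idx$n_fc + seq_len(idx$n_sc)] <- in_blocks(sc_b)
      v <- v + stats::rnorm(L, 0, spec$block_jitter)
      T_mat[k, ] <- v
    }
    # Gram-Schmidt so planted traits are mutually orthogonal
    for (k in seq_len(spec$k_traits)) {
      if (k > 1) {
        prev <- T_mat[seq_len(k - 1), , drop = FALSE]
        T_mat[k, ] <- T_mat[k, ] - as.vector(crossprod(prev %*% T_mat[k, ],
                                                       prev / rowSums(prev^2)))
      }
      T_mat[k, ] <- T_mat[k, ] * spec$trait_scale /
        sqrt(mean(T_mat[k, ]^2))
    }
    T_mat
  })
}

# Planted weights (P x k_traits) and per-profile labels.
synth_weights <- function(spec, seed) {
  P <- spec$n_conditions * spec$n_subjects_per_condition
  condition <- rep(spec$conditions, each = spec$n_subjects_per_condition)
  subject_id <- sprintf("s%03d", seq_len(P))
  with_seed(seed, {
    cond_means <- matrix(0, spec$k_traits, spec$n_conditions,
                         dimnames = list(NULL, spec$conditions))
    # mutually orthogonal condition profiles (each population-sd 1) so
    # distinct sensitive traits are modulated along independent contrasts
    contrasts <- stats::contr.poly(spec$n_conditions) *
      sqrt(spec$n_conditions)
    pick <- sample(ncol(contrasts), spec$k_sensitive)
    for (k in seq_len(spec$k_sensitive))
      cond_means[k, ] <- spec$sensitive_shift * spec$weight_sd *
        sample(c(-1, 1), 1) * contrasts[, pick[k]]
    # equal total expression variance per trait, enforced on the realized
    # draw: subject-level deviations of sensitive traits are residualized
    # against the condition design and scaled to sd exactly `weight_sd`;
    # insensitive traits get a larger subject-level sd in place of the
    # condition-mean spread
    cond_f <- factor(condition, levels = spec$conditions)
    A <- matrix(stats::rnorm(P * spec$k_traits), P, spec$k_traits)
    for (k in seq_len(spec$k_traits)) {
      if (k <= spec$k_sensitive) {
        resid <- A[, k] - stats::ave(A[, k], cond_f)
        A[, k] <- resid / stats::sd(resid) * spec$weight_sd
      } else {
        A[, k] <- A[, k] / stats::sd(A[, k]) * spec$weight_sd *
          sqrt(1 + spec$sensitive_shift^2)
      }
    }
    A <- A + t(cond_means[, match(condition, spec$conditions), drop = FALSE])
    list(A = A, condition = condition, subject_id = subject_id,
         cond_means = cond_means)
  })
}

#' Generate a synthetic hybrid cohort with planted traits
#'
#' Draws the cohort described by a [synthetic_spec()]: each hybrid profile
#' is `sum_k a_pk * t_k + noise`, with the FC and SC blocks clipped to
#' \[-1, 1\] (a warning is raised if clipping touches more than 1% of
#' entries — the trait scale is then too large to be FC-realistic).
#'
#' @param spec a [synthetic_spec()].
#' @param seed overrides `spec$seed` when given.
#' @return list: `hybrid` (a `hybrid_dataset`), `truth` (class
#'   `synthetic_truth`: planted `traits` matrix, `weights`, `condition`,
#'   `subject_id`, `sensitive` flags, `cond_means`, `mask`, `idx`, seed
#'   chain).
#' @export
generate_hybrid_population <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  master <- if (is.null(seed)) spec$seed else as.integer(seed)
  seeds <- spawn_seeds(master, 4L)
  mask <- synth_core_mask(spec, seeds[1])
  idx <- edge_index(spec$n_nodes, mask)
  T_mat <- synth_traits(spec, idx, seeds[2])
  wt <- synth_weights(spec, seeds[3])
  P <- nrow(wt$A)
  L <- ncol(T_mat)
  noise_sd <- spec$noise_rel * spec$trait_scale
  X <- wt$A %*% T_mat
  if (noise_sd > 0)
    X <- X + with_seed(seeds[4], matrix(stats::rnorm(P * L, 0, noise_sd), P, L))
  clipped <- mean(X < -1 | X > 1)
  if (clipped > 0.01)
    warning(sprintf("clipping affected %.2f%% of entries; trait scale too large",
                    100 * clipped))
  X <- pmin(pmax(X, -1), 1)
  h <- hybrid_dataset(X, wt$subject_id, wt$condition, idx)
  truth <- structure(
    list(traits = T_mat, weights = wt$A, condition = wt$condition,
         subject_id = wt$subject_id,
         sensitive = seq_len(spec$k_traits) <= spec$k_sensitive,
         cond_means = wt$cond_means, mask = mask, idx = idx,
         partition = synth_partition(spec$n_nodes),
         seed_chain = c(master = master, seeds)),
    class = "synthetic_truth")
  list(hybrid = h, truth = truth)
}

#' Generate a raw synthetic cohort (FC and SC matrices)
#'
#' End-to-end emulation of the method's inputs: per-profile functional
#' connectomes are the de-vectorized FC halves of a planted hybrid
#' population, and raw structural connectomes share a stochastic-block core
#' topology (present in every subject, so the population common-edge mask
#' is exactly the core) with lognormal streamline weights, per-subject
#' multiplicative jitter, and subject-specific extra edges that do not
#' survive the mask intersection.
#'
#' The planted SC half lives in structural-correlation space; the raw SC
#' generator does not invert that transform, so end-to-end recovery is
#' assessed on the FC half (see [evaluate_recovery()]'s `block = "fc"`).
#'
#' @param spec a [synthetic_spec()].
#' @param seed overrides `spec$seed`.
#' @param dir optional directory; when given, writes per-profile
#'   `fc_*.tsv` / `sc_*.tsv`, `manifest.csv` and `partition.csv`.
#' @return list: `fcs`, `scs` (lists of [connectome]s), `manifest`
#'   (data.frame), `partition`, `mask` (the core), `truth`.
#' @export
generate_raw_connectomes <- function(spec, seed = NULL, dir = NULL) {
  master <- if (is.null(seed)) spec$seed else as.integer(seed)
  pop <- generate_hybrid_population(spec, master)
  h <- pop$hybrid; truth <- pop$truth
  idx <- truth$idx
  P <- nrow(h$X)
  seeds <- spawn_seeds(master + 1L, 2L)
  core_pairs <- truth$mask$pairs
  if (nrow(core_pairs) == 0) stop("core edge set is empty")
  n <- spec$n_nodes
  labs <- names(truth$partition)
  base_w <- with_seed(seeds[1],
                      stats::rlnorm(nrow(core_pairs), spec$sc_meanlog,
                                    spec$sc_sdlog))
  all_pr <- upper_pairs(n)
  noncore <- all_pr[!truth$mask$matrix[all_pr], , drop = FALSE]
  fcs <- vector("list", P); scs <- vector("list", P)
  sub_seeds <- spawn_seeds(seeds[2], P)
  for (p in seq_len(P)) {
    fc_m <- devectorize_trait(c(h$X[p, seq_len(idx$n_fc)],
                                rep(0, idx$n_sc)), idx)$fc
    fcs[[p]] <- connectome(fc_m, "FC", node_labels = labs,
                           subject_id = h$subject_id[p],
                           condition = h$condition[p])
    sc_m <- matrix(0, n, n)
    with_seed(sub_seeds[p], {
      w <- base_w * stats::rlnorm(length(base_w), 0, spec$sc_subject_sdlog)
      sc_m[core_pairs] <- w
      if (nrow(noncore) > 0 && spec$p_extra > 0) {
        extra <- stats::runif(nrow(noncore)) < spec$p_extra
        if (any(extra))
          sc_m[noncore[extra, , drop = FALSE]] <-
            stats::rlnorm(sum(extra), log(5), 0.5)
      }
    })
    sc_m <- sc_m + t(sc_m)
    scs[[p]] <- connectome(sc_m, "SC_RAW", node_labels = labs,
                           subject_id = h$subject_id[p],
                           condition = h$condition[p])
  }
  manifest <- data.frame(subject_id = h$subject_id,
                         condition = h$condition,
                         fc_path = sprintf("fc_%s_%s.tsv", h$subject_id,
                                           h$condition),
                         sc_path = sprintf("sc_%s_%s.tsv", h$subject_id,
                                           h$condition),
                         stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (p in seq_len(P)) {
      write_connectome(fcs[[p]], file.path(dir, manifest$fc_path[p]))
      write_connectome(scs[[p]], file.path(dir, manifest$sc_path[p]))
    }
    write_cohort_manifest(manifest, file.path(dir, "manifest.csv"))
    write_node_partition(truth$partition, file.path(dir, "partition.csv"))
  }
  list(fcs = fcs, scs = scs, manifest = manifest,
       partition = truth$partition, mask = truth$mask, truth = truth)
}

# All injective assignments of the smaller index set into the larger one;
# exact maximization of total |r| (Hungarian-style optimal matching) for
# small K, greedy otherwise.
best_assignment <- function(score) {
  nr <- nrow(score); nc <- ncol(score)
  if (min(nr, nc) <= 6 && max(nr, nc) <= 12) {
    small_rows <- nr <= nc
    k <- min(nr, nc); m <- max(nr, nc)
    perm_rec <- function(v) {
      if (length(v) <= 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (p in perm_rec(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
      out
    }
    best <- NULL; best_val <- -Inf
    for (cols in utils::combn(m, k, simplify = FALSE))
      for (p in perm_rec(cols)) {
        val <- sum(score[cbind(seq_len(k), p)[, if (small_rows) c(1, 2) else c(2, 1), drop = FALSE]])
        if (val > best_val) { best_val <- val; best <- p }
      }
    pairs <- if (small_rows) cbind(seq_len(k), best) else cbind(best, seq_len(k))
  } else {
    sc <- score; pairs <- NULL
    for (i in seq_len(min(nr, nc))) {
      ij <- which(sc == max(sc), arr.ind = TRUE)[1, ]
      pairs <- rbind(pairs, ij)
      sc[ij[1], ] <- -Inf; sc[, ij[2]] <- -Inf
    }
  }
  pairs
}

#' Match recovered traits to planted truth
#'
#' Optimal one-to-one assignment of recovered robust traits to planted
#' traits by |Pearson r| between trait vectors (restricted to the FC block
#' when `block = "fc"`, appropriate for raw-cohort runs where the planted
#' SC half is not realized in the data), reporting per planted trait the
#' trait correlation, the weight correlation over profiles with observed
#' weights, and the ICC of planted vs recovered weights across conditions.
#'
#' @param truth a `synthetic_truth`.
#' @param dec a `decomposition`, or a list of `robust_trait`s.
#' @param block `"hybrid"` (default) or `"fc"`.
#' @return data.frame, one row per planted trait: `true_trait`,
#'   `sensitive`, `matched` (recovered trait id or NA), `trait_r`,
#'   `weight_r`, `icc_true`, `icc_recovered`.
#' @export
evaluate_recovery <- function(truth, dec, block = c("hybrid", "fc")) {
  block <- match.arg(block)
  stopifnot(inherits(truth, "synthetic_truth"))
  traits <- if (inherits(dec, "decomposition")) dec$traits else dec
  Kt <- nrow(truth$traits)
  empty <- data.frame(true_trait = seq_len(Kt), sensitive = truth$sensitive,
                      matched = NA_integer_, trait_r = NA_real_,
                      weight_r = NA_real_, icc_true = NA_real_,
                      icc_recovered = NA_real_)
  if (length(traits) == 0) return(empty)
  R_mat <- do.call(rbind, lapply(traits, function(t) t$trait))
  if (ncol(R_mat) != ncol(truth$traits))
    stop("recovered traits live in a different edge space than the truth")
  cols <- if (block == "fc") seq_len(truth$idx$n_fc) else seq_len(ncol(R_mat))
  score <- abs(stats::cor(t(truth$traits[, cols, drop = FALSE]),
                          t(R_mat[, cols, drop = FALSE])))
  pairs <- best_assignment(score)
  out <- empty
  for (r in seq_len(nrow(pairs))) {
    tt <- pairs[r, 1]; rr <- pairs[r, 2]
    out$matched[tt] <- rr
    out$trait_r[tt] <- score[tt, rr]
    w_rec <- traits[[rr]]$weights
    obs <- !is.na(w_rec)
    if (sum(obs) >= 3)
      out$weight_r[tt] <- abs(stats::cor(truth$weights[obs, tt], w_rec[obs]))
    out$icc_true[tt] <- tryCatch(
      icc_oneway(truth$weights[, tt], truth$condition)$icc,
      error = function(e) NA_real_)
    out$icc_recovered[tt] <- tryCatch(
      icc_oneway(w_rec, truth$condition)$icc, error = function(e) NA_real_)
  }
  out
}
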