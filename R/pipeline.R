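#' Pipeline configuration
#'
#' Resolved settings for [run_pipeline()]: the decomposition configuration
#' plus the sensitivity and mapping parameters. Serializable to JSON so a
#' run report can embed the exact configuration it was produced with.
#'
#' @param decomposition a [decomposition_config()].
#' @param icc_threshold task-sensitivity cut on ICC.
#' @param lo,hi extreme-value percentile bounds for trait mapping.
#' @param exclude_pair_entries passed to [structural_correlation()].
#' @param n_swaps swaps used when the pipeline is asked for a randomized-SC
#'   control.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(decomposition = decomposition_config(),
                            icc_threshold = 0.5, lo = 5, hi = 95,
                            exclude_pair_entries = FALSE, n_swaps = 50000) {
  structure(list(decomposition = decomposition,
                 icc_threshold = icc_threshold, lo = lo, hi = hi,
                 exclude_pair_entries = exclude_pair_entries,
                 n_swaps = n_swaps),
            class = "pipeline_config")
}

#' Run the full hybrid trait-extraction pipeline
#'
#' Orchestrates every stage on a loaded cohort: log-transform the raw SCs,
#' compute the population common-edge mask, convert SCs to structural
#' correlations, assemble the hybrid matrix, decompose it into robust
#' traits, score task sensitivity, and map every robust trait to its joint
#' FC-SC extreme mask and nodal strengths. Input is either a manifest path
#' (matrices are read from disk) or in-memory lists of connectomes.
#'
#' @param fcs list of `FC` [connectome]s, or a manifest CSV path (then
#'   `scs` is ignored and both modalities are read from the manifest).
#' @param scs list of `SC_RAW` [connectome]s, parallel to `fcs`.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory: writes `traits.tsv`,
#'   `weights.tsv`, `sensitivity.csv`, per-trait `mask_<t>.tsv` /
#'   `strength_<t>.csv`, `edge_mask.csv` and `report.json`.
#' @param randomize_sc if TRUE, each SC is degree-preserving randomized
#'   (`config$n_swaps` accepted swaps) before the pipeline runs — the
#'   structural null control.
#' @return list of class `pipeline_result`: `decomposition`,
#'   `sensitivity`, `masks` (list of `joint_mask`), `strengths`,
#'   `edge_mask`, `report` (plain list mirrored to JSON).
#' @export
run_pipeline <- function(fcs, scs = NULL, config = pipeline_config(),
                         out_dir = NULL, randomize_sc = FALSE) {
  if (is.character(fcs)) {
    manifest <- read_cohort_manifest(fcs)
    scs <- mapply(read_connectome, manifest$sc_path, "SC_RAW",
                  manifest$subject_id, manifest$condition, SIMPLIFY = FALSE)
    fcs <- mapply(read_connectome, manifest$fc_path, "FC",
                  manifest$subject_id, manifest$condition, SIMPLIFY = FALSE)
  }
  stopifnot(length(fcs) == length(scs), length(fcs) >= 2)
  if (length(unique(vapply(fcs, function(f) f$condition, character(1)))) < 2)
    stop("sensitivity stage requires >= 2 conditions in the cohort")
  seed <- config$decomposition$seed
  if (randomize_sc) {
    rs <- spawn_seeds(seed + 7L, length(scs))
    scs <- lapply(seq_along(scs), function(i)
      suppressWarnings(
        degree_preserving_randomize(scs[[i]], config$n_swaps,
                                    rs[i]))$connectome)
  }
  scs_log <- lapply(scs, sc_log_transform)
  mask <- common_edge_mask(scs_log)
  idx <- edge_index(nrow(fcs[[1]]$matrix), mask)
  sc_corrs <- lapply(scs_log, structural_correlation, mask = mask,
                     exclude_pair_entries = config$exclude_pair_entries)
  h <- assemble_hybrid(fcs, sc_corrs, idx)
  dec <- decompose_hybrid(h, config$decomposition)
  sens <- if (length(dec$traits) > 0)
    classify_task_sensitive(dec, icc_threshold = config$icc_threshold)
  else data.frame()
  masks <- lapply(dec$traits, joint_fc_sc_mask, idx = idx,
                  lo = config$lo, hi = config$hi)
  strengths <- lapply(masks, nodal_strength)
  report <- list(
    n_profiles = nrow(h$X), n_nodes = idx$n_nodes,
    n_conditions = length(unique(h$condition)),
    edge_mask_count = mask$count, edge_mask_density = mask$density,
    pca_k = dec$pca_k, M_used = dec$M_used,
    runs_converged = dec$runs_converged, n_runs = dec$n_runs,
    n_robust_traits = length(dec$traits),
    frequencies = vapply(dec$traits, function(t) t$frequency, numeric(1)),
    icc = if (nrow(sens)) sens$icc else numeric(0),
    n_task_sensitive = if (nrow(sens)) sum(sens$task_sensitive) else 0L,
    joint_mask_edges = vapply(masks, function(m) m$n_joint, numeric(1)),
    randomized_sc = randomize_sc, seed = seed,
    config = unclass_config(config))
  if (!is.null(out_dir)) write_pipeline_outputs(out_dir, h, dec, sens,
                                                masks, strengths, mask, report)
  structure(list(decomposition = dec, sensitivity = sens, masks = masks,
                 strengths = strengths, edge_mask = mask, hybrid = h,
                 report = report),
            class = "pipeline_result")
}

unclass_config <- function(config) {
  cfg <- unclass(config)
  cfg$decomposition <- unclass(cfg$decomposition)
  cfg
}

write_pipeline_outputs <- function(out_dir, h, dec, sens, masks, strengths,
                                   mask, report) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (length(dec$traits) > 0) {
    T_mat <- t(vapply(dec$traits, function(t) t$trait,
                      numeric(length(dec$traits[[1]]$trait))))
    utils::write.table(t(T_mat), file.path(out_dir, "traits.tsv"),
                       sep = "\t", row.names = FALSE,
                       col.names = paste0("trait", seq_along(dec$traits)))
    W <- vapply(dec$traits, function(t) t$weights, numeric(nrow(h$X)))
    utils::write.table(
      data.frame(subject_id = h$subject_id, condition = h$condition, W,
                 check.names = FALSE),
      file.path(out_dir, "weights.tsv"), sep = "\t", row.names = FALSE)
  }
  if (nrow(sens) > 0)
    utils::write.csv(sens, file.path(out_dir, "sensitivity.csv"),
                     row.names = FALSE)
  for (t in seq_along(masks)) {
    utils::write.table(1 * masks[[t]]$matrix,
                       file.path(out_dir, sprintf("mask_%d.tsv", t)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    utils::write.csv(
      data.frame(node_label = names(strengths[[t]]),
                 strength = unname(strengths[[t]])),
      file.path(out_dir, sprintf("strength_%d.csv", t)), row.names = FALSE)
  }
  utils::write.csv(
    data.frame(i_label = mask$node_labels[mask$pairs[, 1]],
               j_label = mask$node_labels[mask$pairs[, 2]]),
    file.path(out_dir, "edge_mask.csv"), row.names = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("<pipeline_result> %d profiles, %d nodes, mask %d edges",
                     " (%.1f%%)\n  %d robust trait(s), %d task-sensitive\n"),
              r$n_profiles, r$n_nodes, r$edge_mask_count,
              100 * r$edge_mask_density, r$n_robust_traits,
              r$n_task_sensitive))
  invisible(x)
}
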