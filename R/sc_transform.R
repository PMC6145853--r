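#' Log-transform a raw structural connectome
#'
#' Streamline weights span several orders of magnitude; a log10 transform
#' compresses them so that strong bundles do not dominate downstream
#' correlations. Each weight w maps to `log10(1 + w)`, so zeros stay zero
#' (the sparsity pattern is unchanged) and counts up to ~1e5 land in the
#' 0-5 range typical of log-transformed tractography connectomes.
#'
#' @param sc a [connectome] with modality `SC_RAW` and non-negative weights.
#' @return a [connectome], modality `SC_RAW`, log-scale weights.
#' @export
sc_log_transform <- function(sc) {
  stopifnot(inherits(sc, "connectome"))
  if (sc$modality != "SC_RAW") stop("sc_log_transform expects an SC_RAW connectome")
  if (any(sc$matrix < 0)) stop("negative streamline weight in SC")
  out <- sc
  out$matrix <- log10(1 + sc$matrix)
  out
}

#' Canonical upper-triangle pair list
#'
#' All unordered node pairs (i < j) in row-major order:
#' (1,2), (1,3), ..., (1,n), (2,3), ...
#'
#' @param n number of nodes.
#' @return integer matrix with columns `i`, `j` and `n(n-1)/2` rows.
#' @keywords internal
upper_pairs <- function(n) {
  stopifnot(n >= 2)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  cbind(i = i, j = as.integer(j))
}

#' Population common-edge mask
#'
#' The structural-correlation representation is only meaningful on node
#' pairs that are structurally connected; the population mask keeps the
#' pairs with a nonzero structural weight in *every* subject
#' (intersection semantics).
#'
#' @param scs list of `SC_RAW` [connectome]s sharing dimension and node order.
#' @return object of class `edge_mask`: list with `n_nodes`, logical
#'   symmetric `matrix`, row-major `pairs` (i < j) of masked pairs,
#'   `count`, `density` (fraction of all pairs), `provenance` (subject ids).
#' @export
common_edge_mask <- function(scs) {
  if (inherits(scs, "connectome")) scs <- list(scs)
  stopifnot(length(scs) >= 1, all(vapply(scs, inherits, TRUE, "connectome")))
  n <- nrow(scs[[1]]$matrix)
  labs <- scs[[1]]$node_labels
  keep <- matrix(TRUE, n, n)
  for (sc in scs) {
    if (nrow(sc$matrix) != n)
      stop("mismatched connectome dimensions in common_edge_mask")
    keep <- keep & (sc$matrix > 0)
  }
  diag(keep) <- FALSE
  pairs <- upper_pairs(n)
  on_mask <- keep[pairs]
  structure(
    list(n_nodes = n, node_labels = labs, matrix = keep,
         pairs = pairs[on_mask, , drop = FALSE],
         count = sum(on_mask),
         density = sum(on_mask) / nrow(pairs),
         provenance = vapply(scs, function(s) s$subject_id, character(1))),
    class = "edge_mask")
}

#' @export
print.edge_mask <- function(x, ...) {
  cat(sprintf("<edge_mask> %d nodes, %d / %d pairs (%.1f%%), from %d subject(s)\n",
              x$n_nodes, x$count, x$n_nodes * (x$n_nodes - 1) / 2,
              100 * x$density, length(x$provenance)))
  invisible(x)
}

#' Structural correlation of a log-transformed structural connectome
#'
#' For each structurally connected node pair (i, j) in the population mask,
#' the "structural correlation" is the Pearson correlation between row i and
#' row j of the (log-transformed) structural connectome: high values mean
#' the two regions connect similarly to the rest of the network, negative
#' values mean antagonistic connection profiles. Pairs outside the mask are
#' set to zero (structurally absent, not observed). This places SC in the
#' same \[-1, 1\] range as functional connectivity.
#'
#' By default the full rows enter the correlation. With
#' `exclude_pair_entries = TRUE` the columns i and j are dropped from both
#' rows first (matching-index convention), so the pair's own weight and the
#' zero diagonal do not contribute.
#'
#' @param sc log-transformed `SC_RAW` [connectome].
#' @param mask an `edge_mask` from [common_edge_mask()].
#' @param exclude_pair_entries drop columns i, j before correlating.
#' @return a [connectome] with modality `SC_CORR`.
#' @export
structural_correlation <- function(sc, mask, exclude_pair_entries = FALSE) {
  stopifnot(inherits(sc, "connectome"), inherits(mask, "edge_mask"))
  n <- nrow(sc$matrix)
  if (mask$n_nodes != n) stop("mask dimension does not match connectome")
  m <- sc$matrix
  out <- matrix(0, n, n)
  pairs <- mask$pairs
  if (nrow(pairs) > 0) {
    if (!exclude_pair_entries) {
      # zero-variance rows make the correlation undefined; refuse rather
      # than propagate NaN
      sds <- apply(m, 1, stats::sd)
      bad <- unique(c(pairs[, 1], pairs[, 2]))
      bad <- bad[sds[bad] == 0]
      if (length(bad) > 0)
        stop("constant SC row(s) on masked pair: node(s) ",
             paste(sc$node_labels[bad], collapse = ", "))
      cm <- stats::cor(t(m))
      out[pairs] <- cm[pairs]
    } else {
      for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1]; j <- pairs[r, 2]
        xi <- m[i, -c(i, j)]; xj <- m[j, -c(i, j)]
        if (length(xi) < 2 || stats::sd(xi) == 0 || stats::sd(xj) == 0)
          stop("constant SC row on masked pair (",
               sc$node_labels[i], ", ", sc$node_labels[j], ")")
        out[pairs[r, , drop = FALSE]] <- stats::cor(xi, xj)
      }
    }
    out[pairs[, c(2, 1), drop = FALSE]] <- out[pairs]
  }
  out <- pmin(pmax(out, -1), 1)  # guard float overshoot
  connectome(out, "SC_CORR", node_labels = sc$node_labels,
             subject_id = sc$subject_id, condition = sc$condition)
}
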