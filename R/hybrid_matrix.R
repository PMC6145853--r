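#' Edge index for hybrid vectorization
#'
#' Fixes the canonical column order of hybrid profiles: first every node
#' pair i < j in row-major order (the FC block, length n(n-1)/2), then the
#' masked pairs in the same order (the SC block, length |mask|). Downstream
#' decompositions are insensitive to column order, but a fixed serialization
#' makes every output reproducible and de-vectorizable.
#'
#' @param n_nodes number of regions.
#' @param mask an `edge_mask` from [common_edge_mask()] (or NULL for an
#'   FC-only index).
#' @return object of class `edge_index`: `fc_pairs`, `sc_pairs` (2-column
#'   integer matrices), `n_fc`, `n_sc`, `n_nodes`, `node_labels`.
#' @export
edge_index <- function(n_nodes, mask = NULL) {
  fc_pairs <- upper_pairs(n_nodes)
  if (is.null(mask)) {
    sc_pairs <- fc_pairs[0, , drop = FALSE]
    labs <- paste0("n", seq_len(n_nodes))
  } else {
    stopifnot(inherits(mask, "edge_mask"), mask$n_nodes == n_nodes)
    sc_pairs <- mask$pairs
    labs <- mask$node_labels
  }
  structure(
    list(fc_pairs = fc_pairs, sc_pairs = sc_pairs,
         n_fc = nrow(fc_pairs), n_sc = nrow(sc_pairs),
         n_nodes = n_nodes, node_labels = labs),
    class = "edge_index")
}

#' @export
print.edge_index <- function(x, ...) {
  cat(sprintf("<edge_index> %d nodes: FC block %d + SC block %d = %d columns\n",
              x$n_nodes, x$n_fc, x$n_sc, x$n_fc + x$n_sc))
  invisible(x)
}

#' Vectorize one FC / SC-correlation pair into a hybrid profile
#'
#' Concatenates the upper triangle of the functional connectome with the
#' masked entries of the structural-correlation connectome, per the order
#' fixed in the [edge_index()].
#'
#' @param fc `FC` [connectome].
#' @param sc_corr `SC_CORR` [connectome], same nodes and order.
#' @param idx an `edge_index`.
#' @return numeric vector of length `n_fc + n_sc`.
#' @export
vectorize_profile <- function(fc, sc_corr, idx) {
  stopifnot(inherits(idx, "edge_index"))
  if (nrow(fc$matrix) != idx$n_nodes || nrow(sc_corr$matrix) != idx$n_nodes)
    stop("connectome dimension does not match edge index")
  if (!identical(fc$node_labels, sc_corr$node_labels))
    stop("node-order mismatch between FC and SC for subject ", fc$subject_id)
  c(fc$matrix[idx$fc_pairs], sc_corr$matrix[idx$sc_pairs])
}

#' Assemble the cohort hybrid matrix
#'
#' Stacks one hybrid profile per subject-condition into a P x (L_FC + L_SC)
#' matrix whose rows follow the input order; row metadata (subject,
#' condition) is carried alongside and never reordered.
#'
#' @param fcs list of `FC` [connectome]s.
#' @param sc_corrs list of `SC_CORR` [connectome]s, parallel to `fcs`.
#' @param idx an `edge_index`.
#' @return object of class `hybrid_dataset`: `X` (profiles x edges matrix),
#'   `subject_id`, `condition` (per-row), `idx`, `n_nodes`.
#' @export
assemble_hybrid <- function(fcs, sc_corrs, idx) {
  stopifnot(length(fcs) == length(sc_corrs), length(fcs) >= 1)
  X <- matrix(NA_real_, length(fcs), idx$n_fc + idx$n_sc)
  for (p in seq_along(fcs)) {
    v <- tryCatch(vectorize_profile(fcs[[p]], sc_corrs[[p]], idx),
                  error = function(e)
                    stop("profile ", p, " (subject ", fcs[[p]]$subject_id,
                         "): ", conditionMessage(e), call. = FALSE))
    X[p, ] <- v
  }
  hybrid_dataset(X,
                 subject_id = vapply(fcs, function(f) f$subject_id, character(1)),
                 condition = vapply(fcs, function(f) f$condition, character(1)),
                 idx = idx)
}

#' Construct a hybrid dataset from a ready-made matrix
#'
#' @param X numeric P x (n_fc + n_sc) matrix, no missing values; FC and SC
#'   blocks in \[-1, 1\].
#' @param subject_id,condition character vectors of length P.
#' @param idx an `edge_index`.
#' @return a `hybrid_dataset`.
#' @export
hybrid_dataset <- function(X, subject_id, condition, idx) {
  stopifnot(inherits(idx, "edge_index"), is.matrix(X))
  if (ncol(X) != idx$n_fc + idx$n_sc)
    stop("hybrid matrix has ", ncol(X), " columns; edge index expects ",
         idx$n_fc + idx$n_sc)
  if (anyNA(X)) stop("hybrid matrix contains missing values")
  if (max(abs(X)) > 1 + 1e-9)
    stop("hybrid values outside [-1, 1]")
  if (length(subject_id) != nrow(X) || length(condition) != nrow(X))
    stop("row metadata length does not match matrix")
  structure(
    list(X = X, subject_id = as.character(subject_id),
         condition = as.character(condition), idx = idx,
         n_nodes = idx$n_nodes),
    class = "hybrid_dataset")
}

#' @export
print.hybrid_dataset <- function(x, ...) {
  cat(sprintf("<hybrid_dataset> %d profiles x %d edges (FC %d + SC %d), %d condition(s)\n",
              nrow(x$X), ncol(x$X), x$idx$n_fc, x$idx$n_sc,
              length(unique(x$condition))))
  invisible(x)
}

#' Split a hybrid vector back into FC and SC matrices
#'
#' Inverse of [vectorize_profile()] on the masked support: the FC part
#' fills all off-diagonal pairs, the SC part only the masked pairs (zero
#' elsewhere). Used to display a hybrid trait as two brain networks.
#'
#' @param v numeric hybrid vector of length `n_fc + n_sc`.
#' @param idx the `edge_index` the vector was built with.
#' @return list with symmetric matrices `fc` and `sc`.
#' @export
devectorize_trait <- function(v, idx) {
  stopifnot(inherits(idx, "edge_index"))
  if (length(v) != idx$n_fc + idx$n_sc)
    stop("vector length ", length(v), " does not match edge index (",
         idx$n_fc + idx$n_sc, ")")
  n <- idx$n_nodes
  fc <- matrix(0, n, n); sc <- matrix(0, n, n)
  fc[idx$fc_pairs] <- v[seq_len(idx$n_fc)]
  fc[idx$fc_pairs[, c(2, 1), drop = FALSE]] <- v[seq_len(idx$n_fc)]
  if (idx$n_sc > 0) {
    vs <- v[idx$n_fc + seq_len(idx$n_sc)]
    sc[idx$sc_pairs] <- vs
    sc[idx$sc_pairs[, c(2, 1), drop = FALSE]] <- vs
  }
  dimnames(fc) <- dimnames(sc) <- list(idx$node_labels, idx$node_labels)
  list(fc = fc, sc = sc)
}
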