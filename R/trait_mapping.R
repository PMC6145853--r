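#' Extreme-value mask of a vector
#'
#' Marks entries strictly below the `lo`-th or strictly above the `hi`-th
#' percentile. Percentiles use the linear-interpolation convention
#' (`stats::quantile` type 7), so for values 1..100 with (5, 95) the bounds
#' are 5.95 and 95.05 and exactly the bottom five and top five values are
#' selected. For continuous data the expected selected fraction is
#' `(lo + 100 - hi) / 100`.
#'
#' @param values numeric vector (>= 20 finite values recommended).
#' @param lo,hi percentile bounds in \[0, 100\].
#' @return logical vector; all-equal input yields an empty mask with a
#'   warning.
#' @export
percentile_mask <- function(values, lo = 5, hi = 95) {
  stopifnot(lo >= 0, hi <= 100, lo < hi)
  v <- values[is.finite(values)]
  if (length(v) == 0) stop("no finite values")
  if (max(v) == min(v)) {
    warning("all values equal; empty extreme mask")
    return(rep(FALSE, length(values)))
  }
  q <- stats::quantile(v, c(lo, hi) / 100, names = FALSE, type = 7)
  out <- values < q[1] | values > q[2]
  out[!is.finite(values)] <- FALSE
  out
}

#' Joint FC-SC extreme mask of a hybrid trait
#'
#' Splits a hybrid trait into its FC and SC halves, marks the edges outside
#' the (lo, hi) percentile range of each half (SC percentiles over masked
#' edges only — unmasked pairs are structurally absent, not zeros), and
#' keeps the node pairs extreme in *both*: the circuit where the trait's
#' functional and structural signatures coincide.
#'
#' @param trait a `robust_trait` or a numeric hybrid vector.
#' @param idx the `edge_index` of the hybrid space.
#' @param lo,hi percentile bounds (default 5, 95).
#' @return object of class `joint_mask`: symmetric binary `matrix`, the
#'   binary `fc_mask` and `sc_mask` matrices, `lo`, `hi`, counts
#'   (`n_fc_extreme`, `n_sc_extreme`, `n_joint`), and the percentile
#'   convention tag.
#' @export
joint_fc_sc_mask <- function(trait, idx, lo = 5, hi = 95) {
  if (inherits(trait, "robust_trait")) trait <- trait$trait
  stopifnot(inherits(idx, "edge_index"))
  if (length(trait) != idx$n_fc + idx$n_sc)
    stop("trait length does not match edge index")
  n <- idx$n_nodes
  fc_v <- trait[seq_len(idx$n_fc)]
  fc_ext <- percentile_mask(fc_v, lo, hi)
  fc_mask <- matrix(FALSE, n, n)
  fc_mask[idx$fc_pairs[fc_ext, , drop = FALSE]] <- TRUE
  sc_mask <- matrix(FALSE, n, n)
  n_sc_ext <- 0L
  if (idx$n_sc > 0) {
    sc_v <- trait[idx$n_fc + seq_len(idx$n_sc)]
    sc_ext <- percentile_mask(sc_v, lo, hi)
    sc_mask[idx$sc_pairs[sc_ext, , drop = FALSE]] <- TRUE
    n_sc_ext <- sum(sc_ext)
  }
  joint <- fc_mask & sc_mask
  joint <- joint | t(joint)
  fc_full <- fc_mask | t(fc_mask)
  sc_full <- sc_mask | t(sc_mask)
  dimnames(joint) <- list(idx$node_labels, idx$node_labels)
  structure(list(matrix = joint, fc_mask = fc_full, sc_mask = sc_full,
                 lo = lo, hi = hi,
                 n_fc_extreme = sum(fc_ext), n_sc_extreme = n_sc_ext,
                 n_joint = sum(joint) / 2L,
                 percentile_convention = "linear interpolation (type 7)"),
            class = "joint_mask")
}

#' @export
print.joint_mask <- function(x, ...) {
  cat(sprintf("<joint_mask> [%g, %g] percentiles: FC %d, SC %d, joint %d edge(s)\n",
              x$lo, x$hi, x$n_fc_extreme, x$n_sc_extreme, x$n_joint))
  invisible(x)
}

#' Nodal strength of a binary edge mask
#'
#' Number of masked edges incident to each node; the degree sequence of the
#' joint FC-SC circuit, satisfying the handshake identity
#' `sum(strength) == 2 * n_joint`.
#'
#' @param mask a `joint_mask` or a symmetric logical/binary matrix.
#' @return named integer vector of per-node strengths.
#' @export
nodal_strength <- function(mask) {
  m <- if (inherits(mask, "joint_mask")) mask$matrix else mask
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  m <- (m != 0)
  diag(m) <- FALSE
  s <- as.integer(rowSums(m))
  names(s) <- rownames(m)
  s
}
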