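#' Construct a connectome object
#'
#' A connectome is a square, symmetric, zero-diagonal weighted adjacency
#' matrix over brain regions, tagged with a modality:
#' \describe{
#'   \item{FC}{functional connectivity, Pearson correlations in \[-1, 1\]}
#'   \item{SC_RAW}{structural connectivity, non-negative streamline weights
#'     (raw or log-transformed)}
#'   \item{SC_CORR}{structural correlation, Pearson correlations between
#'     structural connection profiles, in \[-1, 1\]}
#' }
#'
#' @param matrix numeric n x n matrix. Symmetrized by averaging with its
#'   transpose when the maximum asymmetry is at most `tol`; larger asymmetry
#'   is an error. The diagonal is forced to zero.
#' @param modality one of `"FC"`, `"SC_RAW"`, `"SC_CORR"`.
#' @param node_labels character vector of region names (defaults to
#'   `n1..nN` or dimnames of `matrix`).
#' @param subject_id,condition optional metadata strings.
#' @param tol symmetry tolerance.
#' @return an object of class `connectome`.
#' @export
connectome <- function(matrix, modality = c("FC", "SC_RAW", "SC_CORR"),
                       node_labels = NULL, subject_id = NA_character_,
                       condition = NA_character_, tol = 1e-9) {
  modality <- match.arg(modality)
  matrix <- as.matrix(matrix)
  if (!is.numeric(matrix)) stop("connectome matrix must be numeric")
  if (nrow(matrix) != ncol(matrix))
    stop("shape error: connectome matrix must be square (got ",
         nrow(matrix), " x ", ncol(matrix), ")")
  if (anyNA(matrix)) stop("connectome matrix contains missing values")
  asym <- max(abs(matrix - t(matrix)))
  if (asym > tol)
    stop("symmetry error: maximum asymmetry ", format(asym),
         " exceeds tolerance ", format(tol))
  matrix <- (matrix + t(matrix)) / 2
  diag(matrix) <- 0
  n <- nrow(matrix)
  if (is.null(node_labels)) {
    node_labels <- rownames(matrix)
    if (is.null(node_labels)) node_labels <- paste0("n", seq_len(n))
  }
  if (length(node_labels) != n)
    stop("node_labels length (", length(node_labels),
         ") does not match matrix dimension (", n, ")")
  if (modality %in% c("FC", "SC_CORR")) {
    if (any(matrix < -1 - 1e-12 | matrix > 1 + 1e-12))
      stop("range error: ", modality, " values must lie in [-1, 1]")
  } else {
    if (any(matrix < 0))
      stop("range error: SC_RAW weights must be non-negative")
  }
  dimnames(matrix) <- list(node_labels, node_labels)
  structure(
    list(matrix = matrix, node_labels = as.character(node_labels),
         modality = modality, subject_id = as.character(subject_id),
         condition = as.character(condition)),
    class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %s, %d nodes", x$modality, length(x$node_labels)))
  if (!is.na(x$subject_id)) cat(", subject", x$subject_id)
  if (!is.na(x$condition)) cat(", condition", x$condition)
  cat(sprintf(", %d nonzero edges\n", sum(x$matrix[upper.tri(x$matrix)] != 0)))
  invisible(x)
}

#' Read a connectome from a tab-separated matrix file
#'
#' The file holds an n x n numeric table, one row per line, tab-separated.
#' An optional first line `#labels:<tab><lab1><tab><lab2>...` carries node
#' labels; node order is always the file order.
#'
#' @param path file path.
#' @inheritParams connectome
#' @return a [connectome].
#' @export
read_connectome <- function(path, modality = c("FC", "SC_RAW", "SC_CORR"),
                            subject_id = NA_character_,
                            condition = NA_character_) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("connectome file not found: ", path)
  lines <- readLines(path)
  labels <- NULL
  if (length(lines) > 0 && startsWith(lines[[1]], "#labels:")) {
    labels <- strsplit(sub("^#labels:\t?", "", lines[[1]]), "\t", fixed = TRUE)[[1]]
    lines <- lines[-1]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty connectome file: ", path)
  rows <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1)
    stop("shape error: ragged rows in ", path)
  m <- matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
  if (nrow(m) != ncol(m))
    stop("shape error: connectome matrix must be square (got ",
         nrow(m), " x ", ncol(m), ")")
  connectome(m, modality, node_labels = labels,
             subject_id = subject_id, condition = condition)
}

#' Write a connectome to a tab-separated matrix file
#'
#' Inverse of [read_connectome()]: values round-trip to full double
#' precision and node labels are preserved verbatim.
#'
#' @param con a [connectome].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(con, path) {
  stopifnot(inherits(con, "connectome"))
  header <- paste0("#labels:\t", paste(con$node_labels, collapse = "\t"))
  body <- apply(con$matrix, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A CSV with header `subject_id,condition,fc_path,sc_path`, one row per
#' subject-condition profile. Relative paths are resolved against the
#' manifest's directory.
#'
#' @param path CSV file path.
#' @param check_paths verify that every fc/sc file exists (default TRUE).
#' @return a data.frame with the four columns plus attribute `conditions`
#'   (sorted unique condition labels).
#' @export
read_cohort_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "condition", "fc_path", "sc_path")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("manifest is empty: ", path)
  key <- paste(df$subject_id, df$condition, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (subject_id, condition) pair(s) in manifest: ",
         paste(unique(df$subject_id[duplicated(key)]), collapse = ", "))
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  df$fc_path <- resolve(df$fc_path)
  df$sc_path <- resolve(df$sc_path)
  if (check_paths) {
    bad <- c(df$fc_path[!file.exists(df$fc_path)],
             df$sc_path[!file.exists(df$sc_path)])
    if (length(bad) > 0)
      stop("manifest references missing file(s): ",
           paste(utils::head(bad, 3), collapse = ", "))
  }
  attr(df, "conditions") <- sort(unique(df$condition))
  df
}

#' Write a cohort manifest CSV
#' @param manifest data.frame with columns subject_id, condition, fc_path, sc_path.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_manifest <- function(manifest, path) {
  utils::write.csv(
    manifest[, c("subject_id", "condition", "fc_path", "sc_path")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a node partition (region to resting-state network assignment)
#'
#' Two-column CSV `node_label,rsn` assigning each region to one
#' resting-state network (e.g. VIS, SM, DA, VA, L, FP, DMN, SUBC).
#'
#' @param path CSV path.
#' @param node_labels optional character vector; when given, the partition
#'   must cover exactly these nodes.
#' @return named character vector: `rsn` labels named by node label.
#' @export
read_node_partition <- function(path, node_labels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("node_label", "rsn") %in% names(df)))
    stop("partition must have columns node_label,rsn")
  if (anyDuplicated(df$node_label))
    stop("node assigned more than once in partition")
  part <- stats::setNames(as.character(df$rsn), df$node_label)
  if (!is.null(node_labels)) {
    if (length(part) != length(node_labels) ||
        !setequal(names(part), node_labels))
      stop("partition does not cover the connectome's ",
           length(node_labels), " nodes exactly")
    part <- part[node_labels]
  }
  part
}

#' Write a node partition CSV
#' @param partition named character vector (names = node labels, values = RSN).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_node_partition <- function(partition, path) {
  utils::write.csv(
    data.frame(node_label = names(partition), rsn = unname(partition)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
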