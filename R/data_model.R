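#' Construct a binary edge mask
#'
#' An edge mask is a symmetric node-by-node binary indicator matrix marking
#' the unordered node pairs ("edges") that belong to a network, e.g. the
#' high-attention network of a sustained-attention connectome-based
#' predictive model. The diagonal is always zero; self-pairs are not edges.
#'
#' @param matrix Square numeric matrix with entries in \{0, 1\}. A strictly
#'   triangular matrix (one triangle all zero) is mirrored into a symmetric
#'   one; a full matrix must already be symmetric.
#' @param label Free-text label carried along for reporting.
#' @return An object of class `edge_mask`: a list with elements `matrix`
#'   (symmetric integer 0/1 matrix), `n_nodes`, `edge_count` (number of
#'   upper-triangle 1s) and `label`.
#' @examples
#' m <- matrix(0, 4, 4); m[1, 2] <- m[2, 1] <- 1
#' edge_mask(m, label = "toy")
#' @export
edge_mask <- function(matrix, label = "") {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix)) {
    stop("edge mask must be a square matrix", call. = FALSE)
  }
  if (!is.numeric(matrix) || anyNA(matrix)) {
    stop("edge mask entries must be numeric and non-missing", call. = FALSE)
  }
  if (!all(matrix %in% c(0, 1))) {
    stop("edge mask entries must all be 0 or 1", call. = FALSE)
  }
  if (any(diag(matrix) != 0)) {
    stop("edge mask diagonal must be zero (self-pairs are not edges)",
         call. = FALSE)
  }
  lower_zero <- all(matrix[lower.tri(matrix)] == 0)
  upper_zero <- all(matrix[upper.tri(matrix)] == 0)
  if ((lower_zero || upper_zero) && !(lower_zero && upper_zero)) {
    matrix <- matrix + t(matrix)  # mirror a strictly triangular input
  } else if (!isTRUE(all.equal(matrix, t(matrix), check.attributes = FALSE))) {
    stop("edge mask must be symmetric or strictly triangular", call. = FALSE)
  }
  storage.mode(matrix) <- "integer"
  dimnames(matrix) <- NULL
  structure(
    list(matrix = matrix,
         n_nodes = nrow(matrix),
         edge_count = sum(matrix[upper.tri(matrix)]),
         label = label),
    class = "edge_mask"
  )
}

#' @export
print.edge_mask <- function(x, ...) {
  cat(sprintf("<edge_mask> %s: %d nodes, %d edges\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              x$n_nodes, x$edge_count))
  invisible(x)
}

#' Construct a Fisher-z functional connectome
#'
#' A connectome holds the Fisher z-transformed Pearson correlations between
#' every pair of parcellation nodes, plus a per-node validity flag: nodes
#' without usable data keep their row/column (as NaN) so masks stay aligned.
#'
#' @param values Square numeric matrix of Fisher-z values, symmetric on the
#'   valid nodes. The diagonal is not an edge and is stored as 0.
#' @param valid_nodes Logical vector, one flag per node. Defaults to marking
#'   invalid any node whose off-diagonal row is entirely NaN/NA.
#' @param meta Optional named list of session metadata (subject, condition,
#'   run type, ...).
#' @return An object of class `conn_matrix`.
#' @export
conn_matrix <- function(values, valid_nodes = NULL, meta = NULL) {
  if (!is.matrix(values) || nrow(values) != ncol(values) || !is.numeric(values)) {
    stop("connectome values must be a square numeric matrix", call. = FALSE)
  }
  n <- nrow(values)
  if (is.null(valid_nodes)) {
    valid_nodes <- vapply(seq_len(n), function(i) {
      if (n == 1L) TRUE else !all(is.na(values[i, -i]))
    }, logical(1))
  }
  if (length(valid_nodes) != n || !is.logical(valid_nodes)) {
    stop("valid_nodes must be a logical vector of length n_nodes", call. = FALSE)
  }
  vv <- values[valid_nodes, valid_nodes, drop = FALSE]
  if (length(vv) > 1 &&
      !isTRUE(all.equal(vv, t(vv), tolerance = 1e-8, check.attributes = FALSE))) {
    stop("connectome must be symmetric on its valid nodes", call. = FALSE)
  }
  diag(values) <- 0
  values[!valid_nodes, ] <- NaN
  values[, !valid_nodes] <- NaN
  dimnames(values) <- NULL
  structure(list(values = values, valid_nodes = valid_nodes, meta = meta),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> %d nodes (%d valid)",
              length(x$valid_nodes), sum(x$valid_nodes)))
  if (!is.null(x$meta$subject_id)) {
    cat(sprintf(" [%s %s %s]", x$meta$subject_id,
                x$meta$condition %||% "", x$meta$run_type %||% ""))
  }
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Upper-triangle linear indices of an n x n matrix, column-major, as used for
# edge vectorisation throughout the package.
upper_tri_index <- function(n) which(upper.tri(diag(n)))
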