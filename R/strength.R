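# Network-strength scoring: mean Fisher-z connectivity over the edges of a
# binary mask, the high-minus-low attention difference score, application of
# a fixed linear behavioural model, and the canonical-network grid.

#' Mean Fisher-z connectivity over a masked edge set ("network strength")
#'
#' Averages the connectome's values over the mask's upper-triangle edges.
#' Edges touching an invalid node (NaN) are dropped from the mean; if no
#' usable edge remains the strength is undefined and `NA` is returned
#' (never silently 0).
#'
#' @param conn A [conn_matrix()].
#' @param mask An [edge_mask()] on the same node set.
#' @return Mean Fisher-z over usable mask edges (`NA` if none), with
#'   attribute `n_edges_used` giving the number of edges entering the mean.
#' @export
network_strength <- function(conn, mask) {
  stopifnot(inherits(conn, "conn_matrix"), inherits(mask, "edge_mask"))
  if (nrow(conn$values) != mask$n_nodes) {
    stop("connectome and mask node counts differ", call. = FALSE)
  }
  ut <- upper.tri(conn$values)
  vals <- conn$values[ut & mask$matrix == 1L]
  usable <- vals[!is.na(vals)]
  out <- if (length(usable) == 0L) NA_real_ else mean(usable)
  attr(out, "n_edges_used") <- length(usable)
  out
}

#' Score a connectome against a high/low mask pair
#'
#' @param conn A [conn_matrix()].
#' @param high_mask,low_mask [edge_mask()] objects, e.g. the high- and
#'   low-attention networks of a sustained-attention predictive model.
#' @return One-row tibble with `high`, `low`, `diff` (= high - low) and the
#'   edge counts actually used after NaN-edge drop.
#' @export
attention_strength <- function(conn, high_mask, low_mask) {
  hi <- network_strength(conn, high_mask)
  lo <- network_strength(conn, low_mask)
  tibble::tibble(
    high = as.numeric(hi),
    low = as.numeric(lo),
    diff = as.numeric(hi) - as.numeric(lo),
    n_edges_used_high = attr(hi, "n_edges_used"),
    n_edges_used_low = attr(lo, "n_edges_used")
  )
}

#' High-minus-low attention difference score
#'
#' @param result A row as produced by [attention_strength()] (anything with
#'   `high` and `low` fields).
#' @return `high - low`; `NA` propagates if either strength is undefined.
#' @export
attention_diff <- function(result) {
  result$high - result$low
}

#' Fixed linear model mapping a difference score to predicted task sensitivity
#'
#' The published sustained-attention predictive model pairs its edge masks
#' with a linear coefficient and offset that convert a high-minus-low
#' difference score into a predicted d-prime. Those published constants live
#' alongside the published masks, not in this package: the defaults here are
#' placeholders (identity model) and real analyses must supply values.
#'
#' @param coefficient Slope on the difference score.
#' @param intercept Additive offset, in predicted d-prime units.
#' @return An object of class `sacpm_model`.
#' @export
sacpm_model <- function(coefficient = 1, intercept = 0) {
  stopifnot(is.finite(coefficient), is.finite(intercept))
  structure(list(coefficient = coefficient, intercept = intercept),
            class = "sacpm_model")
}

#' @param diff Difference score(s), high minus low network strength.
#' @param model A [sacpm_model()].
#' @rdname sacpm_model
#' @export
sacpm_predict <- function(diff, model) {
  stopifnot(inherits(model, "sacpm_model"))
  model$coefficient * diff + model$intercept
}

#' Mean connectivity grid over canonical network pairs
#'
#' Given an assignment of every node to one of k canonical resting-state
#' networks, computes the k x k grid whose (A, B) cell is the mean Fisher-z
#' connectivity over all unordered node pairs spanning networks A and B
#' (within-network pairs on the diagonal; self-pairs excluded). NaN edges
#' are dropped; a network with fewer than two valid nodes has an undefined
#' diagonal cell (`NA`).
#'
#' @param conn A [conn_matrix()].
#' @param assignment Factor or vector of length n_nodes labelling each
#'   node's network; the grid rows/columns follow `levels(factor(assignment))`.
#' @return Symmetric k x k numeric matrix with dimnames set to the labels.
#' @export
canonical_grid <- function(conn, assignment) {
  stopifnot(inherits(conn, "conn_matrix"))
  n <- nrow(conn$values)
  if (length(assignment) != n) {
    stop("assignment must label every node", call. = FALSE)
  }
  f <- factor(assignment)
  labs <- levels(f)
  k <- length(labs)
  grid <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  ut <- upper.tri(conn$values)
  for (a in seq_len(k)) {
    for (b in a:k) {
      sel <- ut &
        ((outer(f == labs[a], f == labs[b])) |
           (outer(f == labs[b], f == labs[a])))
      vals <- conn$values[sel]
      vals <- vals[!is.na(vals)]
      if (length(vals)) grid[a, b] <- grid[b, a] <- mean(vals)
    }
  }
  grid
}
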