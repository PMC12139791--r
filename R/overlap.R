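# Hypergeometric edge-set overlap statistics: do two brain networks share
# more edges than expected if each were an independent draw from the set of
# all possible edges?

#' Total number of possible edges in an n-node parcellation
#'
#' `n_nodes * (n_nodes - 1) / 2` unordered node pairs; for the standard
#' 268-node whole-brain atlas this is 35,778.
#'
#' @param n_nodes Number of parcellation nodes (>= 2).
#' @return Integer-valued count of possible edges.
#' @examples
#' total_edges(268)  # 35778
#' @export
total_edges <- function(n_nodes) {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || n_nodes < 2) {
    stop("n_nodes must be a single count >= 2", call. = FALSE)
  }
  n_nodes * (n_nodes - 1) / 2
}

#' Count edges shared by two masks
#'
#' @param mask_a,mask_b [edge_mask()] objects on the same node set.
#' @return Number of upper-triangle positions where both masks are 1.
#' @export
overlap_count <- function(mask_a, mask_b) {
  stopifnot(inherits(mask_a, "edge_mask"), inherits(mask_b, "edge_mask"))
  if (mask_a$n_nodes != mask_b$n_nodes) {
    stop("masks must share a node count", call. = FALSE)
  }
  ut <- upper.tri(mask_a$matrix)
  sum(mask_a$matrix[ut] == 1L & mask_b$matrix[ut] == 1L)
}

#' Hypergeometric tail probability of an edge-set overlap
#'
#' With `M` possible edges in total, one network of `K` edges and another of
#' `n` edges drawn without replacement, the overlap `X` follows a
#' hypergeometric distribution. The default convention reports the
#' enrichment tail `P(X >= x) = 1 - CDF(x - 1)`: the probability of sharing
#' at least the observed number of edges by chance. `convention = "greater"`
#' gives the strict tail `P(X > x) = 1 - CDF(x)` instead.
#'
#' @param x Observed overlap count.
#' @param K Edge count of the first network.
#' @param n Edge count of the second network.
#' @param M Total possible edges (see [total_edges()]).
#' @param convention `"at_least"` (default, `P(X >= x)`) or `"greater"`
#'   (`P(X > x)`).
#' @return Upper-tail probability in `[0, 1]`.
#' @examples
#' hypergeom_overlap_p(x = 5, K = 757, n = 135, M = total_edges(268))
#' @export
hypergeom_overlap_p <- function(x, K, n, M,
                                convention = c("at_least", "greater")) {
  convention <- match.arg(convention)
  stopifnot(x >= 0, K >= 0, n >= 0, K <= M, n <= M)
  if (x > min(K, n)) {
    stop(sprintf("infeasible overlap: x = %d > min(K, n) = %d",
                 x, min(K, n)), call. = FALSE)
  }
  q <- if (convention == "at_least") x - 1 else x
  phyper(q, m = K, n = M - K, k = n, lower.tail = FALSE)
}

#' Tabulate directional overlap tests between mask pairs
#'
#' One row per (network, selection) pairing — e.g. high-attention against
#' drug-positive edges, low-attention against drug-negative edges, and the
#' cross pairings — each with its overlap count and hypergeometric tail
#' probability.
#'
#' @param mask_pairs Named list of two-element lists/pairs of [edge_mask()]
#'   objects: `list(label = list(mask1, mask2), ...)`.
#' @param M Total possible edges; defaults to [total_edges()] of the masks'
#'   node count.
#' @param convention Tail convention, see [hypergeom_overlap_p()].
#' @return Tibble: `pair`, `network_1`, `K`, `network_2`, `n`, `x`, `p`.
#' @export
overlap_table <- function(mask_pairs, M = NULL,
                          convention = c("at_least", "greater")) {
  convention <- match.arg(convention)
  rows <- lapply(seq_along(mask_pairs), function(i) {
    pr <- mask_pairs[[i]]
    a <- pr[[1]]
    b <- pr[[2]]
    total <- if (is.null(M)) total_edges(a$n_nodes) else M
    x <- overlap_count(a, b)
    tibble::tibble(
      pair = names(mask_pairs)[i] %||% sprintf("pair_%d", i),
      network_1 = a$label, K = a$edge_count,
      network_2 = b$label, n = b$edge_count,
      x = x,
      p = hypergeom_overlap_p(x, a$edge_count, b$edge_count, total,
                              convention = convention)
    )
  })
  do.call(rbind, rows)
}
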