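# Functional connectome construction and run-level quality control.

# Motion QC cutoffs: exclusion is triggered only when a metric is strictly
# beyond its bound ("exceeding" / "greater than" / "more than").
QC_MAX_DISPLACEMENT_MM <- 3
QC_MEAN_MOTION_MM <- 0.15
QC_FRAC_CENSORED <- 0.5

#' Compute a Fisher-z functional connectome from node time series
#'
#' Functional connectivity between two parcellation nodes is the Fisher
#' z-transformed Pearson correlation of their time series, `atanh(r)`.
#' Correlations are clipped to +/-(1 - 1e-7) before the transform so that
#' degenerate r = +/-1 pairs stay finite. Invalid nodes keep their place in
#' the matrix with NaN rows/columns.
#'
#' @param ts Node-by-time numeric matrix (one row per node).
#' @param valid_nodes Logical vector of per-node validity; defaults to all
#'   valid. Rows of invalid nodes are ignored.
#' @param meta Optional metadata list passed through to the result.
#' @return A [conn_matrix()] with `atanh`-transformed correlations off the
#'   diagonal.
#' @examples
#' ts <- matrix(rnorm(5 * 100), 5, 100)
#' compute_fc(ts)
#' @export
compute_fc <- function(ts, valid_nodes = NULL, meta = NULL) {
  if (!is.matrix(ts) || !is.numeric(ts)) {
    stop("ts must be a numeric node-by-time matrix", call. = FALSE)
  }
  n_nodes <- nrow(ts)
  if (ncol(ts) < 3L) stop("need at least 3 timepoints", call. = FALSE)
  if (is.null(valid_nodes)) valid_nodes <- rep(TRUE, n_nodes)
  stopifnot(length(valid_nodes) == n_nodes)
  rs <- rowSums(ts)
  ss <- rowSums(ts * ts)
  vars <- (ss - rs^2 / ncol(ts)) / (ncol(ts) - 1)
  degenerate <- valid_nodes & (is.na(vars) | vars <= 0)
  if (any(degenerate)) {
    stop("zero-variance time series for valid node(s): ",
         paste(which(degenerate), collapse = ", "), call. = FALSE)
  }
  z <- matrix(NaN, n_nodes, n_nodes)
  if (sum(valid_nodes) >= 2L) {
    r <- cor(t(ts[valid_nodes, , drop = FALSE]))
    r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
    z[valid_nodes, valid_nodes] <- atanh(r)
  }
  diag(z) <- 0
  conn_matrix(z, valid_nodes = valid_nodes, meta = meta)
}

#' Apply run-level quality-control exclusions
#'
#' A run is excluded when its maximum censored displacement exceeds 3 mm,
#' its average censored motion exceeds 0.15 mm, or more than 50% of its
#' frames were censored — all strict inequalities, so a run exactly at a
#' bound is kept. Runs with missing QC metrics are excluded with reason
#' `missing_data`; runs with missing parcellation nodes are excluded only
#' under `strict_nodes = TRUE` (otherwise missing nodes are handled at the
#' node level downstream).
#'
#' @param records Session manifest tibble ([read_manifest()] layout).
#' @param strict_nodes If `TRUE`, any missing node excludes the run.
#' @return A tibble with the manifest columns plus `included` (logical) and
#'   `reasons` (list-column of character vectors, empty iff included).
#' @export
qc_filter <- function(records, strict_nodes = FALSE) {
  n <- nrow(records)
  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    r <- character(0)
    md <- records$max_displacement_mm[i]
    mm <- records$mean_censored_motion_mm[i]
    fc <- records$frac_censored[i]
    if (is.na(md) || is.na(mm) || is.na(fc)) r <- c(r, "missing_data")
    if (!is.na(md) && md > QC_MAX_DISPLACEMENT_MM) r <- c(r, "max_disp")
    if (!is.na(mm) && mm > QC_MEAN_MOTION_MM) r <- c(r, "mean_motion")
    if (!is.na(fc) && fc > QC_FRAC_CENSORED) r <- c(r, "censor_frac")
    mn <- records$missing_nodes[[i]]
    if (strict_nodes && length(mn) > 0) r <- c(r, "missing_nodes")
    reasons[[i]] <- r
  }
  out <- tibble::as_tibble(records)
  out$included <- lengths(reasons) == 0L
  out$reasons <- reasons
  out
}

#' Combine the two runs of a two-run task into one connectome
#'
#' When both runs survive QC their connectivity matrices are averaged
#' elementwise; when only one survives it is used as-is; when neither does
#' the session has no usable connectome.
#'
#' @param run1,run2 [conn_matrix()] objects or `NULL` for an excluded run.
#' @return A [conn_matrix()], or `NULL` when both runs are absent.
#' @export
combine_doors <- function(run1, run2) {
  if (is.null(run1) && is.null(run2)) return(NULL)
  if (is.null(run2)) return(run1)
  if (is.null(run1)) return(run2)
  stopifnot(inherits(run1, "conn_matrix"), inherits(run2, "conn_matrix"))
  if (!identical(dim(run1$values), dim(run2$values))) {
    stop("cannot combine runs with different node counts", call. = FALSE)
  }
  conn_matrix((run1$values + run2$values) / 2,
              valid_nodes = run1$valid_nodes & run2$valid_nodes,
              meta = run1$meta)
}

#' List subjects usable in a paired condition contrast
#'
#' A subject enters an MA-versus-placebo comparison of a given run type only
#' with a QC-included run of that type in both conditions.
#'
#' @param decisions Output of [qc_filter()].
#' @param run_type One of `"rest"`, `"mid"`, `"doors1"`, `"doors2"`; or a
#'   vector (e.g. `c("doors1", "doors2")`) in which case a usable run of any
#'   listed type counts for a condition.
#' @return Character vector of subject ids, sorted.
#' @export
pair_conditions <- function(decisions, run_type) {
  keep <- decisions$included & decisions$run_type %in% run_type
  d <- decisions[keep, , drop = FALSE]
  has_ma <- unique(d$subject_id[d$condition == "MA"])
  has_pl <- unique(d$subject_id[d$condition == "PL"])
  sort(intersect(has_ma, has_pl))
}
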