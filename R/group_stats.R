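# Paired condition inference: paired t-tests with Cohen's d, the
# Bonferroni-corrected canonical-grid contrast, change scores, and
# cross-run / brain-behaviour correlations.

#' Paired t-test with Cohen's d
#'
#' A one-sample t-test against zero on the within-subject differences
#' `x - y`, two-tailed, with the paired-design standardised effect size
#' `cohens_d = mean(diff) / sd(diff)` (so `t = d * sqrt(n)`).
#'
#' @param x,y Equal-length paired numeric vectors (condition A and B values
#'   for the same subjects, in the same order).
#' @return One-row tibble: `estimate` (mean difference), `t`, `df`, `p`
#'   (two-tailed), `cohens_d`, `n`.
#' @examples
#' paired_t(c(2, 3, 4, 6, 8), c(1, 1, 1, 2, 3))
#' @export
paired_t <- function(x, y = NULL) {
  if (is.null(y)) y <- rep(0, length(x))
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  keep <- !(is.na(x) | is.na(y))
  d <- x[keep] - y[keep]
  n <- length(d)
  if (n < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble::tibble(estimate = 0, t = 0, df = n - 1, p = 1,
                            cohens_d = 0, n = n))
    }
    stop("differences have zero variance", call. = FALSE)
  }
  tt <- t.test(d, mu = 0)
  tibble::tibble(
    estimate = mean(d),
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    cohens_d = mean(d) / sd(d),
    n = n
  )
}

#' Cellwise paired contrast of canonical-network grids
#'
#' For every cell of the k x k canonical-network grid, tests whether the
#' group-mean within-subject difference (condition A minus condition B)
#' deviates from zero with a two-tailed one-sample t-test, then flags cells
#' whose raw p falls below the Bonferroni threshold `alpha / k^2`. The full
#' k^2-cell family is used (symmetric duplicates included), matching the
#' conventional 8 x 8 grid corrected at 0.05/64. Subjects with an undefined
#' value in a cell are dropped from that cell only.
#'
#' @param grids_a,grids_b Lists of per-subject k x k grids
#'   ([canonical_grid()] output), matched by position (same subject order).
#' @param alpha Family-wise error rate before division; default 0.05.
#' @return List of class `grid_contrast`: `t`, `p`, `estimate` (k x k
#'   matrices), `significant` (logical k x k), `n` (per-cell pair counts),
#'   `threshold` (= alpha / k^2).
#' @export
grid_contrast <- function(grids_a, grids_b, alpha = 0.05) {
  stopifnot(length(grids_a) == length(grids_b), length(grids_a) >= 2)
  k <- nrow(grids_a[[1]])
  labs <- rownames(grids_a[[1]])
  a <- simplify2array(grids_a)  # k x k x n
  b <- simplify2array(grids_b)
  tmat <- pmat <- est <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  nmat <- matrix(0L, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k)) {
    for (j in i:k) {
      diffs <- a[i, j, ] - b[i, j, ]
      diffs <- diffs[!is.na(diffs)]
      nmat[i, j] <- nmat[j, i] <- length(diffs)
      if (length(diffs) >= 2 && sd(diffs) > 0) {
        res <- paired_t(diffs)
        tmat[i, j] <- tmat[j, i] <- res$t
        pmat[i, j] <- pmat[j, i] <- res$p
        est[i, j] <- est[j, i] <- res$estimate
      } else if (length(diffs) >= 2) {
        tmat[i, j] <- tmat[j, i] <- 0
        pmat[i, j] <- pmat[j, i] <- 1
        est[i, j] <- est[j, i] <- mean(diffs)
      }
    }
  }
  threshold <- alpha / k^2
  structure(
    list(t = tmat, p = pmat, estimate = est,
         significant = !is.na(pmat) & pmat < threshold,
         n = nmat, threshold = threshold),
    class = "grid_contrast"
  )
}

#' @export
print.grid_contrast <- function(x, ...) {
  k <- nrow(x$t)
  cat(sprintf("<grid_contrast> %dx%d cells, Bonferroni threshold %.2e, %d significant\n",
              k, k, x$threshold, sum(x$significant, na.rm = TRUE)))
  print(round(x$t, 2))
  invisible(x)
}

#' Per-subject condition change scores
#'
#' Pairs two named value vectors by subject and returns the within-subject
#' difference (condition A minus condition B, conventionally drug minus
#' placebo). Subjects present in only one condition are dropped with a
#' message.
#'
#' @param values_a,values_b Named numeric vectors (names are subject ids).
#' @return Named numeric vector of `values_a - values_b` over the common
#'   subjects, in sorted subject order.
#' @export
change_scores <- function(values_a, values_b) {
  if (is.null(names(values_a)) || is.null(names(values_b))) {
    stop("values must be named by subject", call. = FALSE)
  }
  common <- sort(intersect(names(values_a), names(values_b)))
  dropped <- setdiff(union(names(values_a), names(values_b)), common)
  if (length(dropped)) {
    message("change_scores: dropping unpaired subject(s): ",
            paste(dropped, collapse = ", "))
  }
  values_a[common] - values_b[common]
}

#' Correlate condition-induced changes across run types
#'
#' Pearson correlation (two-tailed) between two per-subject change-score
#' vectors, e.g. the attention-network change at rest versus during a task,
#' used to ask whether a drug's network effect is consistent across scan
#' contexts.
#'
#' @param delta_a,delta_b Named numeric change-score vectors; paired by
#'   subject name when both are named, by position otherwise.
#' @return One-row tibble: `r`, `p`, `n`.
#' @export
consistency_corr <- function(delta_a, delta_b) {
  if (!is.null(names(delta_a)) && !is.null(names(delta_b))) {
    common <- sort(intersect(names(delta_a), names(delta_b)))
    delta_a <- delta_a[common]
    delta_b <- delta_b[common]
  }
  keep <- !(is.na(delta_a) | is.na(delta_b))
  a <- delta_a[keep]
  b <- delta_b[keep]
  if (length(a) < 3L) stop("need at least 3 common subjects", call. = FALSE)
  ct <- cor.test(a, b, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}

#' Correlate network change with behavioural change
#'
#' Same machinery as [consistency_corr()], named for its use: does a
#' drug-induced change in network strength track the change in task
#' sensitivity (d-prime) of the same subjects?
#'
#' @param delta_net Named per-subject network-strength change scores.
#' @param delta_dprime Named per-subject d-prime change scores.
#' @return One-row tibble: `r`, `p`, `n`.
#' @export
brain_behavior_corr <- function(delta_net, delta_dprime) {
  consistency_corr(delta_net, delta_dprime)
}
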