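# Condition classification from edge vectors: paired leave-one-subject-out
# linear SVM, pair-flip permutation null, fold-averaged weight maps, and
# top-weight edge-set extraction.

#' Build a scan-by-edge design matrix from paired connectomes
#'
#' Vectorises each connectome's upper triangle into a feature row. Edges
#' that are NaN in any scan (e.g. touching a node missing in some subject)
#' are dropped globally so every scan shares one feature space.
#'
#' @param conns List of [conn_matrix()] objects, each with `meta$subject_id`
#'   and `meta$condition` ("MA"/"PL"). A subject may contribute one or two
#'   scans.
#' @return List of class `cpm_design`: `x` (scans x edges matrix), `y`
#'   (factor with levels MA, PL), `subject` (character), `edge_index`
#'   (upper-triangle linear indices of the retained edges), `n_nodes`,
#'   `n_dropped_edges`.
#' @export
build_design <- function(conns) {
  stopifnot(length(conns) >= 2)
  n_nodes <- nrow(conns[[1]]$values)
  ut <- upper_tri_index(n_nodes)
  x <- t(vapply(conns, function(cn) {
    stopifnot(inherits(cn, "conn_matrix"))
    if (nrow(cn$values) != n_nodes) {
      stop("all connectomes must share one node count", call. = FALSE)
    }
    cn$values[ut]
  }, numeric(length(ut))))
  keep <- colSums(is.na(x)) == 0L
  if (!any(keep)) stop("no edge is finite in every scan", call. = FALSE)
  if (any(!keep)) {
    message(sprintf("build_design: dropping %d edge(s) with missing values",
                    sum(!keep)))
  }
  y <- vapply(conns, function(cn) cn$meta$condition, character(1))
  stopifnot(all(y %in% CONDITIONS))
  structure(
    list(x = x[, keep, drop = FALSE],
         y = factor(y, levels = CONDITIONS),
         subject = vapply(conns, function(cn) as.character(cn$meta$subject_id),
                          character(1)),
         edge_index = ut[keep],
         n_nodes = n_nodes,
         n_dropped_edges = sum(!keep)),
    class = "cpm_design"
  )
}

# Mirror an edge-weight vector back into a symmetric node x node matrix;
# edges absent from the design are NA.
devectorize_weights <- function(w, edge_index, n_nodes) {
  m <- matrix(NA_real_, n_nodes, n_nodes)
  m[edge_index] <- w
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 0
  m
}

# Fit a linear soft-margin SVM and return the primal weight vector and bias
# oriented so that a positive decision value (and a positive weight) points
# towards the first condition level (MA). The linear-kernel decision value
# x.w - rho is computed directly from the dual solution, which agrees with
# predict() to numerical precision and avoids its per-call overhead in the
# cross-validation and permutation loops.
fit_linear_svm <- function(x, y, cost) {
  if (nlevels(droplevels(y)) < 2L) {
    stop("training set contains a single class", call. = FALSE)
  }
  model <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE,
                      fitted = FALSE, na.action = stats::na.pass)
  w <- drop(crossprod(model$coefs, model$SV))
  rho <- model$rho
  # e1071 orients decision values towards the class seen first in training
  if (model$levels[model$labels[1]] != CONDITIONS[1]) {
    w <- -w
    rho <- -rho
  }
  list(weights = w, rho = rho)
}

# Predict condition labels from an oriented linear fit.
predict_linear <- function(fit, x) {
  f <- drop(x %*% fit$weights) - fit$rho
  ifelse(f > 0, CONDITIONS[1], CONDITIONS[2])
}

#' Paired leave-one-subject-out SVM classification of condition
#'
#' One cross-validation fold per subject: all of that subject's scans (the
#' drug and placebo scan when both are usable, a single scan otherwise) are
#' held out together, a linear soft-margin SVM is trained on every other
#' subject's scans, and the held-out scans are predicted. Accuracy is pooled
#' over all held-out scans. Per-fold primal weight vectors are retained and
#' averaged (as-is, no sign alignment) into a symmetric node-by-node weight
#' map. Features are used unstandardised: Fisher-z edges already share a
#' scale.
#'
#' @param design A `cpm_design` from [build_design()].
#' @param cost Soft-margin regularisation parameter C of the SVM.
#' @param keep_weights If `FALSE`, skip weight extraction (used internally
#'   by the permutation null, where only accuracy matters).
#' @return List of class `classifier_report`: `predictions` (tibble with
#'   subject, truth, predicted), `accuracy`, `fold_weights` (matrix, one row
#'   per fold), `mean_weights` (node x node symmetric matrix), `n_subjects`,
#'   `cost`.
#' @export
loso_paired_cv <- function(design, cost = 1, keep_weights = TRUE) {
  stopifnot(inherits(design, "cpm_design"))
  subjects <- unique(design$subject)
  if (length(subjects) < 3L) stop("need at least 3 subjects", call. = FALSE)
  preds <- truth <- character(0)
  pred_subj <- character(0)
  fold_w <- if (keep_weights) {
    matrix(NA_real_, length(subjects), ncol(design$x))
  } else NULL
  for (si in seq_along(subjects)) {
    held <- design$subject == subjects[si]
    fit <- fit_linear_svm(design$x[!held, , drop = FALSE],
                          design$y[!held], cost)
    p <- predict_linear(fit, design$x[held, , drop = FALSE])
    preds <- c(preds, p)
    truth <- c(truth, as.character(design$y[held]))
    pred_subj <- c(pred_subj, design$subject[held])
    if (keep_weights) fold_w[si, ] <- fit$weights
  }
  out <- list(
    predictions = tibble::tibble(subject = pred_subj, truth = truth,
                                 predicted = preds),
    accuracy = mean(preds == truth),
    fold_weights = fold_w,
    mean_weights = if (keep_weights) {
      devectorize_weights(colMeans(fold_w), design$edge_index, design$n_nodes)
    } else NULL,
    n_subjects = length(subjects),
    cost = cost
  )
  class(out) <- "classifier_report"
  out
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %d subjects, %d held-out scans, accuracy %.2f%%\n",
              x$n_subjects, nrow(x$predictions), 100 * x$accuracy))
  if (!is.null(x$perm_p)) {
    cat(sprintf("  permutation null: %d draws, p = %.4g\n",
                length(x$perm_null), x$perm_p))
  }
  invisible(x)
}

#' Permutation null for paired classification accuracy
#'
#' Breaks the condition-connectome association while preserving the paired
#' design: each permutation independently flips each subject's drug/placebo
#' labels with probability 1/2 (`scheme = "pairflip"`, the default) or
#' reshuffles all labels freely (`scheme = "full"`), then reruns the full
#' leave-one-subject-out cross-validation. The p-value uses the add-one
#' estimator `(1 + #{null >= observed}) / (1 + n_perm)`, which can never be
#' exactly zero under a finite permutation sample.
#'
#' @param design A `cpm_design` from [build_design()].
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed for the permutation draws.
#' @param observed Observed accuracy to compare against; computed from
#'   `design` via [loso_paired_cv()] when omitted.
#' @param scheme `"pairflip"` or `"full"`.
#' @param cost SVM regularisation parameter, as in [loso_paired_cv()].
#' @return List: `null_accuracies` (length `n_perm`), `observed`, `perm_p`.
#' @export
permutation_test <- function(design, n_perm = 1000, seed = 1,
                             observed = NULL,
                             scheme = c("pairflip", "full"), cost = 1) {
  stopifnot(inherits(design, "cpm_design"))
  scheme <- match.arg(scheme)
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  if (is.null(observed)) {
    observed <- loso_paired_cv(design, cost = cost, keep_weights = FALSE)$accuracy
  }
  subjects <- unique(design$subject)
  null_acc <- numeric(n_perm)
  set.seed(seed)
  flip_one <- function(lab) factor(ifelse(lab == "MA", "PL", "MA"),
                                   levels = CONDITIONS)
  for (b in seq_len(n_perm)) {
    perm <- design
    if (scheme == "pairflip") {
      flip <- setNames(runif(length(subjects)) < 0.5, subjects)
      sel <- flip[perm$subject]
      perm$y[sel] <- flip_one(perm$y[sel])
    } else {
      perm$y <- sample(perm$y)
    }
    null_acc[b] <- loso_paired_cv(perm, cost = cost,
                                  keep_weights = FALSE)$accuracy
  }
  list(null_accuracies = null_acc,
       observed = observed,
       perm_p = (1 + sum(null_acc >= observed)) / (1 + n_perm))
}

#' Select top-weight edges from a fold-averaged weight map
#'
#' Under the `"absolute"` rule, edges with mean weight strictly above
#' `pos_threshold` form the positive (drug-weighted) mask and edges strictly
#' below `neg_threshold` the negative (placebo-weighted) mask. Under the
#' `"percentile"` rule, the `floor(q/100 * n_finite)` most-positive and
#' most-negative edges are taken per side.
#'
#' @param mean_weights Symmetric node x node weight matrix
#'   (`mean_weights` of a [loso_paired_cv()] report); NA edges are ignored.
#' @param rule `"absolute"` or `"percentile"`.
#' @param pos_threshold,neg_threshold Weight cutoffs for the absolute rule.
#' @param q Percentage per side for the percentile rule (e.g. 2.5).
#' @return List of class `edge_selection`: `positive_mask`, `negative_mask`
#'   ([edge_mask()] objects, disjoint by construction), `n_positive`,
#'   `n_negative`, `rule`, and the thresholds actually applied.
#' @export
select_edges <- function(mean_weights, rule = c("absolute", "percentile"),
                         pos_threshold = NULL, neg_threshold = NULL,
                         q = 2.5) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(mean_weights), nrow(mean_weights) == ncol(mean_weights))
  n_nodes <- nrow(mean_weights)
  ut <- upper_tri_index(n_nodes)
  w <- mean_weights[ut]
  finite <- which(is.finite(w))
  pos <- neg <- logical(length(w))
  if (rule == "absolute") {
    if (is.null(pos_threshold) || is.null(neg_threshold)) {
      stop("absolute rule needs pos_threshold and neg_threshold", call. = FALSE)
    }
    pos[finite] <- w[finite] > pos_threshold
    neg[finite] <- w[finite] < neg_threshold
  } else {
    n_take <- floor(q / 100 * length(finite))
    if (n_take > 0) {
      ord <- finite[order(w[finite], decreasing = TRUE)]
      pos[head(ord, n_take)] <- TRUE
      neg[rev(ord)[seq_len(n_take)]] <- TRUE
      pos_threshold <- min(w[pos])
      neg_threshold <- max(w[neg])
    }
  }
  if (any(pos & neg)) {
    stop("positive and negative selections overlap; lower q or widen thresholds",
         call. = FALSE)
  }
  if (!any(pos) && !any(neg)) {
    warning("edge selection is empty under the given rule", call. = FALSE)
  }
  to_mask <- function(sel, label) {
    m <- matrix(0L, n_nodes, n_nodes)
    m[ut[sel]] <- 1L
    edge_mask(m + t(m), label = label)
  }
  structure(
    list(positive_mask = to_mask(pos, "positive"),
         negative_mask = to_mask(neg, "negative"),
         n_positive = sum(pos), n_negative = sum(neg),
         rule = rule,
         pos_threshold = pos_threshold, neg_threshold = neg_threshold),
    class = "edge_selection"
  )
}
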