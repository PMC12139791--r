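# End-to-end analysis chain on an in-memory dataset: QC -> connectomes ->
# network strength -> paired statistics -> classification -> overlap.

#' Run the full paired-condition analysis on a synthetic dataset
#'
#' Chains every stage of the package on one dataset: run-level QC and
#' condition pairing, Fisher-z connectome computation, high/low network
#' strength and difference scores, paired t-tests, the Bonferroni-corrected
#' canonical-grid contrast, paired leave-one-subject-out SVM classification
#' with a permutation null, top-weight edge selection, and the
#' hypergeometric overlap table of the selected edges against the planted
#' attention and arousal masks.
#'
#' @param dataset A `synth_dataset` from [gen_condition_dataset()] (or any
#'   list with the same fields built from real data).
#' @param run_type Run type to analyse (must be generated in the dataset).
#' @param n_perm Permutations for the classification null.
#' @param cost SVM regularisation parameter.
#' @param seed Seed for the permutation draws.
#' @param select_rule,q,pos_threshold,neg_threshold Edge-selection rule and
#'   parameters, see [select_edges()].
#' @return List: `qc` (decisions), `paired_subjects`, `strengths` (tibble
#'   per subject x condition), `tests` (paired t-tests on high, low and
#'   diff), `grid` ([grid_contrast()] result), `classifier`
#'   ([loso_paired_cv()] report with `perm_null`/`perm_p` fields filled),
#'   `selection` ([select_edges()] result), `overlap` ([overlap_table()]
#'   tibble).
#' @export
run_pipeline <- function(dataset, run_type = "rest", n_perm = 100, cost = 1,
                         seed = 1, select_rule = "percentile", q = 2.5,
                         pos_threshold = NULL, neg_threshold = NULL) {
  stopifnot(run_type %in% dataset$config$run_types)
  qc <- qc_filter(dataset$manifest)
  paired <- pair_conditions(qc, run_type)
  if (length(paired) < 3L) {
    stop("fewer than 3 subjects with usable runs in both conditions",
         call. = FALSE)
  }
  included <- qc[qc$included & qc$run_type == run_type &
                   qc$subject_id %in% paired, ]
  conns <- lapply(seq_len(nrow(included)), function(i) {
    key <- included$path[i]
    compute_fc(dataset$timeseries[[key]],
               meta = list(subject_id = included$subject_id[i],
                           condition = included$condition[i],
                           run_type = run_type))
  })
  strengths <- do.call(rbind, lapply(conns, function(cn) {
    cbind(tibble::tibble(subject_id = cn$meta$subject_id,
                         condition = cn$meta$condition),
          attention_strength(cn, dataset$masks$high_attention,
                             dataset$masks$low_attention))
  }))
  by_cond <- function(col, cond) {
    v <- strengths[strengths$condition == cond, ]
    setNames(v[[col]], v$subject_id)[paired]
  }
  tests <- do.call(rbind, lapply(c("high", "low", "diff"), function(col) {
    cbind(tibble::tibble(measure = col),
          paired_t(by_cond(col, "MA"), by_cond(col, "PL")))
  }))
  grids <- lapply(conns, canonical_grid, assignment = dataset$assignment)
  is_ma <- vapply(conns, function(cn) cn$meta$condition == "MA", logical(1))
  subj_of <- vapply(conns, function(cn) cn$meta$subject_id, character(1))
  ord_ma <- match(paired, subj_of[is_ma])
  ord_pl <- match(paired, subj_of[!is_ma])
  grid <- grid_contrast(grids[is_ma][ord_ma], grids[!is_ma][ord_pl])
  design <- build_design(conns)
  report <- loso_paired_cv(design, cost = cost)
  perm <- permutation_test(design, n_perm = n_perm, seed = seed,
                           observed = report$accuracy, cost = cost)
  report$perm_null <- perm$null_accuracies
  report$perm_p <- perm$perm_p
  selection <- select_edges(report$mean_weights, rule = select_rule,
                            pos_threshold = pos_threshold,
                            neg_threshold = neg_threshold, q = q)
  pairs <- list(
    high_vs_positive = list(dataset$masks$high_attention, selection$positive_mask),
    low_vs_negative = list(dataset$masks$low_attention, selection$negative_mask),
    high_vs_negative = list(dataset$masks$high_attention, selection$negative_mask),
    low_vs_positive = list(dataset$masks$low_attention, selection$positive_mask)
  )
  if (!is.null(dataset$masks$arousal_pos)) {
    pairs <- c(pairs, list(
      arousal_pos_vs_positive = list(dataset$masks$arousal_pos,
                                     selection$positive_mask),
      arousal_neg_vs_negative = list(dataset$masks$arousal_neg,
                                     selection$negative_mask),
      arousal_pos_vs_negative = list(dataset$masks$arousal_pos,
                                     selection$negative_mask),
      arousal_neg_vs_positive = list(dataset$masks$arousal_neg,
                                     selection$positive_mask)
    ))
  }
  overlap <- overlap_table(pairs)
  list(qc = qc, paired_subjects = paired, strengths = strengths,
       tests = tests, grid = grid, classifier = report,
       selection = selection, overlap = overlap)
}
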