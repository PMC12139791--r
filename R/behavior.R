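# Go/no-go sustained-attention scoring (signal-detection d-prime), and the
# subject groupings used in moderator analyses.

#' Score a go/no-go continuous-performance run with d-prime
#'
#' A hit is a response on a go trial; a false alarm is a response on a no-go
#' trial. Sensitivity is the difference between the standardised rates,
#' `d' = qnorm(hit_rate) - qnorm(fa_rate)`. Extreme rates are corrected by
#' the standard 1/(2N) rule before standardising: a rate of 0 becomes
#' 1/(2N) and a rate of 1 becomes 1 - 1/(2N), with N the number of trials
#' of that type.
#'
#' @param trials Trial table ([read_gradcpt_trials()] layout): columns
#'   `category` ("go"/"nogo") and `responded` (logical).
#' @return One-row tibble: `n_go`, `n_nogo`, `hits`, `false_alarms`,
#'   `hit_rate`, `fa_rate` (post-correction) and `dprime`.
#' @examples
#' trials <- gen_gradcpt(gradcpt_config(d_true = 2, seed = 1))
#' score_gradcpt(trials)
#' @export
score_gradcpt <- function(trials) {
  go <- trials$category == "go"
  nogo <- trials$category == "nogo"
  n_go <- sum(go)
  n_nogo <- sum(nogo)
  if (n_go == 0L) stop("no go trials; d-prime undefined", call. = FALSE)
  if (n_nogo == 0L) stop("no no-go trials; d-prime undefined", call. = FALSE)
  hits <- sum(trials$responded[go])
  fas <- sum(trials$responded[nogo])
  hr <- correct_rate(hits / n_go, n_go)
  far <- correct_rate(fas / n_nogo, n_nogo)
  tibble::tibble(
    n_go = n_go, n_nogo = n_nogo, hits = hits, false_alarms = fas,
    hit_rate = hr, fa_rate = far, dprime = qnorm(hr) - qnorm(far)
  )
}

correct_rate <- function(rate, n) {
  if (rate == 0) 1 / (2 * n) else if (rate == 1) 1 - 1 / (2 * n) else rate
}

#' Median-split subjects into high and low performers
#'
#' Subjects strictly above the median score form the high group; subjects at
#' or below the median form the low group (ties at the median go to low, a
#' deterministic convention). With an even number of distinct-score subjects
#' this yields equal halves.
#'
#' @param scores Named numeric vector, one score per subject.
#' @return List with character-vector elements `high` and `low`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (is.null(names(scores))) {
    stop("scores must be named by subject", call. = FALSE)
  }
  if (length(unique(scores)) == 1L) {
    stop("all scores identical; no median split exists", call. = FALSE)
  }
  m <- median(scores)
  list(high = names(scores)[scores > m],
       low = names(scores)[scores <= m])
}

#' Partition subjects by order of drug administration
#'
#' Uses the manifest's `session_index` column to find each subject's
#' first-session condition.
#'
#' @param records Session manifest tibble with `subject_id`, `condition`
#'   and `session_index` columns.
#' @return List with character-vector elements `MA_first` and `PL_first`.
#' @export
order_split <- function(records) {
  if (!"session_index" %in% names(records) ||
      all(is.na(records$session_index))) {
    stop("session order metadata (session_index) is required", call. = FALSE)
  }
  first <- records[!is.na(records$session_index) & records$session_index == 1L,
                   c("subject_id", "condition")]
  first <- unique(first)
  dup <- duplicated(first$subject_id)
  if (any(dup)) {
    stop("conflicting first-session condition for subject(s): ",
         paste(unique(first$subject_id[dup]), collapse = ", "), call. = FALSE)
  }
  all_subj <- unique(records$subject_id)
  no_order <- setdiff(all_subj, first$subject_id)
  if (length(no_order)) {
    stop("no first-session record for subject(s): ",
         paste(no_order, collapse = ", "), call. = FALSE)
  }
  list(MA_first = sort(first$subject_id[first$condition == "MA"]),
       PL_first = sort(first$subject_id[first$condition == "PL"]))
}
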