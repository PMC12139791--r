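# Synthetic paired-condition connectome data with planted network effects.
#
# The generator emulates the statistical structure the analysis assumes: a
# cohort of subjects scanned under a drug (MA) and a placebo (PL) condition,
# whose node time series share a base correlation structure, and whose MA
# covariance is shifted up on the edges of a "high" mask and down on the
# edges of a "low" mask. A subject-level Gaussian multiplier on the planted
# shift creates the between-subject variability a paired design sees, and is
# shared across run types so drug effects are consistent across contexts.

#' Configuration for the synthetic connectome generator
#'
#' Defaults mirror the acquisition they emulate: a 268-node parcellation and
#' 210 volumes per run (a 7-minute run at TR = 2 s). `effect_size` is the
#' correlation-scale shift planted on mask edges in the drug condition; its
#' default, together with `heterogeneity = 1.0`, was calibrated by
#' simulation so the within-subject high-minus-low contrast has Cohen's
#' d of about 1 at the package's 40-node test scale (with estimation noise
#' negligible, d is approximately `1 / heterogeneity`).
#'
#' @param n_subjects Number of subjects (each scanned in both conditions).
#' @param n_nodes Number of parcellation nodes (tests typically use 30-60).
#' @param n_timepoints Volumes per run; must be >= 20 for estimable
#'   correlations.
#' @param effect_size Correlation-scale shift planted on mask edges in the
#'   MA condition (+ on high edges, - on low edges); >= 0.
#' @param heterogeneity SD of the subject-level Gaussian multiplier
#'   (centred at 1) scaling each subject's planted effect.
#' @param noise_sd Residual SD of the node signals (does not affect
#'   correlations; kept for realistic signal amplitudes).
#' @param mask_sizes Named integer vector of mask edge counts. The default
#'   scales the canonical 268-node sizes (757 high-attention, 630
#'   low-attention, 469/555 arousal, 500/500 valence) in proportion to the
#'   number of possible edges.
#' @param mask_overlap Number of edges shared between the high and low
#'   attention masks (default 0: disjoint by construction).
#' @param run_types Run types generated per subject and condition.
#' @param qc_fail_frac Fraction of runs planted (independently per run) to
#'   fail motion QC.
#' @param seed Integer seed; identical configs give byte-identical data.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 40, n_nodes = 268, n_timepoints = 210,
                         effect_size = 0.11, heterogeneity = 1.0,
                         noise_sd = 1, mask_sizes = NULL, mask_overlap = 0,
                         run_types = "rest", qc_fail_frac = 0, seed = 1) {
  stopifnot(n_subjects >= 1, n_nodes >= 4, n_timepoints >= 20,
            effect_size >= 0, heterogeneity >= 0, noise_sd > 0,
            qc_fail_frac >= 0, qc_fail_frac <= 1,
            all(run_types %in% RUN_TYPES))
  if (is.null(mask_sizes)) {
    scale <- total_edges(n_nodes) / total_edges(268)
    mask_sizes <- c(high_attention = max(1L, round(757 * scale)),
                    low_attention = max(1L, round(630 * scale)),
                    arousal_pos = max(1L, round(469 * scale)),
                    arousal_neg = max(1L, round(555 * scale)),
                    valence_pos = max(1L, round(500 * scale)),
                    valence_neg = max(1L, round(500 * scale)))
  }
  structure(
    list(n_subjects = n_subjects, n_nodes = n_nodes,
         n_timepoints = n_timepoints, effect_size = effect_size,
         heterogeneity = heterogeneity, noise_sd = noise_sd,
         mask_sizes = mask_sizes, mask_overlap = mask_overlap,
         run_types = run_types, qc_fail_frac = qc_fail_frac,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate the named edge-mask set of a synthetic study
#'
#' Draws the high- and low-attention masks disjointly (up to
#' `mask_overlap` shared edges) from the set of all possible edges, then
#' draws arousal and valence mask pairs independently at random, so their
#' overlap with the attention masks is itself hypergeometric. Deterministic
#' under the config seed.
#'
#' @param config A [synth_config()].
#' @return Named list of [edge_mask()] objects, plus attribute none; names
#'   follow `config$mask_sizes`.
#' @export
gen_masks <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  sizes <- config$mask_sizes
  n_edges <- total_edges(config$n_nodes)
  if (any(sizes > n_edges)) {
    stop("requested mask size exceeds the number of possible edges",
         call. = FALSE)
  }
  need_disjoint <- sizes["high_attention"] + sizes["low_attention"] -
    config$mask_overlap
  if (!is.na(need_disjoint) && need_disjoint > n_edges) {
    stop("high + low mask sizes exceed the available edges", call. = FALSE)
  }
  set.seed(config$seed)
  ut <- upper_tri_index(config$n_nodes)
  make <- function(idx, label) {
    m <- matrix(0L, config$n_nodes, config$n_nodes)
    m[ut[idx]] <- 1L
    edge_mask(m + t(m), label = label)
  }
  masks <- list()
  hi_idx <- lo_idx <- integer(0)
  if ("high_attention" %in% names(sizes)) {
    hi_idx <- sample.int(n_edges, sizes["high_attention"])
    masks$high_attention <- make(hi_idx, "high_attention")
  }
  if ("low_attention" %in% names(sizes)) {
    shared <- if (config$mask_overlap > 0) {
      sample(hi_idx, min(config$mask_overlap, length(hi_idx)))
    } else integer(0)
    rest <- sample(setdiff(seq_len(n_edges), hi_idx),
                   sizes["low_attention"] - length(shared))
    lo_idx <- c(shared, rest)
    masks$low_attention <- make(lo_idx, "low_attention")
  }
  for (nm in setdiff(names(sizes), c("high_attention", "low_attention"))) {
    if (sizes[nm] > 0) {
      masks[[nm]] <- make(sample.int(n_edges, sizes[nm]), nm)
    } else {
      masks[[nm]] <- make(integer(0), nm)
    }
  }
  masks
}

#' Assign nodes to canonical resting-state networks
#'
#' Splits the nodes into `n_networks` contiguous, near-equal blocks labelled
#' after the eight canonical resting-state networks (medial frontal,
#' frontoparietal, default mode, subcortical-cerebellar, motor, visual I,
#' visual II, visual association).
#'
#' @param n_nodes Number of nodes.
#' @param n_networks Number of networks (default 8).
#' @return Factor of length `n_nodes`.
#' @export
gen_canonical_assignment <- function(n_nodes, n_networks = 8) {
  labels <- c("MedialFrontal", "Frontoparietal", "DefaultMode",
              "SubcortCerebellar", "Motor", "VisualI", "VisualII",
              "VisualAssoc")
  if (n_networks != 8) labels <- paste0("Net", seq_len(n_networks))
  if (n_nodes < 2 * n_networks) {
    stop("need at least 2 nodes per network", call. = FALSE)
  }
  f <- labels[ceiling(seq_len(n_nodes) / (n_nodes / n_networks))]
  factor(f, levels = labels)
}

# Base correlation structure shared by all subjects: a low-rank factor model
# cov2cor(L L' + I), giving mild positive and negative correlations.
base_correlation <- function(n_nodes, n_factors = 3, loading_sd = 0.35) {
  L <- matrix(rnorm(n_nodes * n_factors, sd = loading_sd), n_nodes, n_factors)
  stats::cov2cor(tcrossprod(L) + diag(n_nodes))
}

# Plant a condition effect on mask edges of a correlation matrix, clip to
# keep entries inside (-1, 1), and repair to the nearest positive-definite
# correlation matrix only when the Cholesky check fails.
plant_effect <- function(R0, high, low, shift) {
  R <- R0
  if (!is.null(high)) R[high$matrix == 1L] <- R[high$matrix == 1L] + shift
  if (!is.null(low)) R[low$matrix == 1L] <- R[low$matrix == 1L] - shift
  R <- pmin(pmax(R, -0.97), 0.97)
  diag(R) <- 1
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) {
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE, maxit = 200)$mat)
    ch <- tryCatch(chol(R), error = function(e) NULL)
    if (is.null(ch)) {
      stop("planted covariance is not positive definite after repair",
           call. = FALSE)
    }
  }
  ch
}

#' Generate a paired-condition multi-subject dataset
#'
#' For every subject, condition and run type, draws correlated node time
#' series from the base covariance; in the MA condition the correlations on
#' high-mask edges are raised and on low-mask edges lowered by
#' `effect_size` times the subject's multiplier (shared across run types).
#' Emits a session manifest with motion QC metrics, a planted fraction of
#' which fail QC, and a randomised administration order per subject.
#'
#' @param config A [synth_config()].
#' @param masks Optional mask set from [gen_masks()]; generated from the
#'   config when omitted. The high/low attention masks carry the planted
#'   effect.
#' @return List of class `synth_dataset`: `timeseries` (named list of
#'   node x time matrices keyed `subject_condition_runtype`), `manifest`
#'   (tibble in the [read_manifest()] layout plus `session_index`),
#'   `masks`, `assignment` (canonical-network factor), `subject_effect`
#'   (named per-subject multipliers), `config`.
#' @export
gen_condition_dataset <- function(config, masks = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(masks)) masks <- gen_masks(config)
  set.seed(config$seed + 1L)
  n <- config$n_nodes
  subjects <- sprintf("S%03d", seq_len(config$n_subjects))
  R0 <- base_correlation(n)
  chol_base <- chol(R0)
  m_s <- setNames(1 + config$heterogeneity * rnorm(config$n_subjects),
                  subjects)
  ts <- list()
  rows <- list()
  for (s in subjects) {
    ma_first <- runif(1) < 0.5
    chol_ma <- if (config$effect_size > 0) {
      plant_effect(R0, masks$high_attention, masks$low_attention,
                   config$effect_size * m_s[s])
    } else chol_base
    for (cond in CONDITIONS) {
      ch <- if (cond == "MA") chol_ma else chol_base
      for (rt in config$run_types) {
        Z <- matrix(rnorm(config$n_timepoints * n, sd = config$noise_sd),
                    config$n_timepoints, n)
        key <- paste(s, cond, rt, sep = "_")
        ts[[key]] <- t(Z %*% ch)
        fail <- runif(1) < config$qc_fail_frac
        qc <- if (fail) {
          mode <- sample(3, 1)
          c(md = if (mode == 1) runif(1, 3.5, 6) else runif(1, 0.2, 1.5),
            mm = if (mode == 2) runif(1, 0.2, 0.4) else runif(1, 0.02, 0.1),
            fc = if (mode == 3) runif(1, 0.55, 0.9) else runif(1, 0, 0.3))
        } else {
          c(md = runif(1, 0.2, 1.5), mm = runif(1, 0.02, 0.1),
            fc = runif(1, 0, 0.3))
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject_id = s, condition = cond, run_type = rt, path = key,
          max_displacement_mm = round(qc[["md"]], 4),
          mean_censored_motion_mm = round(qc[["mm"]], 4),
          frac_censored = round(qc[["fc"]], 4),
          missing_nodes = "",
          session_index = if ((cond == "MA") == ma_first) 1L else 2L
        )
      }
    }
  }
  manifest <- do.call(rbind, rows)
  manifest$missing_nodes <- lapply(manifest$missing_nodes, function(x) integer(0))
  structure(
    list(timeseries = ts, manifest = manifest, masks = masks,
         assignment = gen_canonical_assignment(n),
         subject_effect = m_s, config = config),
    class = "synth_dataset"
  )
}

#' Write a synthetic dataset to disk in the package's text formats
#'
#' Time series go to `<dir>/ts/<key>.tsv` (node x time, tab-delimited), the
#' manifest to `<dir>/manifest.csv` (with `path` pointing at the time-series
#' files), masks to `<dir>/masks/<name>.txt` and the canonical assignment to
#' `<dir>/assignment.csv`.
#'
#' @param dataset A `synth_dataset` from [gen_condition_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_condition_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synth_dataset"))
  dir.create(file.path(dir, "ts"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  for (key in names(dataset$timeseries)) {
    lines <- apply(dataset$timeseries[[key]], 1L, function(row) {
      paste(format_full(row), collapse = "\t")
    })
    writeLines(lines, file.path(dir, "ts", paste0(key, ".tsv")))
  }
  manifest <- dataset$manifest
  manifest$path <- file.path("ts", paste0(manifest$path, ".tsv"))
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  for (nm in names(dataset$masks)) {
    write_edge_mask(dataset$masks[[nm]], file.path(dir, "masks",
                                                   paste0(nm, ".txt")))
  }
  write.csv(data.frame(node = seq_along(dataset$assignment),
                       network = as.character(dataset$assignment)),
            file.path(dir, "assignment.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Configuration for the synthetic go/no-go trial generator
#'
#' Defaults emulate a 750-trial continuous performance run with 90% go
#' (respond) and 10% no-go (withhold) trials.
#'
#' @param n_trials Number of trials.
#' @param p_nogo Probability a trial is no-go.
#' @param d_true True signal-detection sensitivity of the simulated
#'   observer.
#' @param criterion Decision bias c (0 = unbiased).
#' @param seed Integer seed.
#' @return List of class `gradcpt_config`.
#' @export
gradcpt_config <- function(n_trials = 750, p_nogo = 0.10, d_true = 2,
                           criterion = 0, seed = 1) {
  stopifnot(n_trials > 0, p_nogo > 0, p_nogo < 1)
  structure(list(n_trials = n_trials, p_nogo = p_nogo, d_true = d_true,
                 criterion = criterion, seed = as.integer(seed)),
            class = "gradcpt_config")
}

#' Generate go/no-go trials from an equal-variance signal-detection observer
#'
#' Trial categories are i.i.d. Bernoulli(`p_nogo`); the observer responds on
#' a go trial with probability `pnorm(d_true/2 - criterion)` (hits) and on a
#' no-go trial with probability `pnorm(-d_true/2 - criterion)` (false
#' alarms), the equal-variance signal-detection model. With `d_true = 0` and
#' `criterion = 0` both rates are 0.5.
#'
#' @param config A [gradcpt_config()].
#' @return Trial-table tibble (`trial_index`, `category`, `responded`),
#'   deterministic under the config seed.
#' @export
gen_gradcpt <- function(config) {
  stopifnot(inherits(config, "gradcpt_config"))
  set.seed(config$seed)
  nogo <- runif(config$n_trials) < config$p_nogo
  p_resp <- ifelse(nogo,
                   pnorm(-config$d_true / 2 - config$criterion),
                   pnorm(config$d_true / 2 - config$criterion))
  tibble::tibble(
    trial_index = seq_len(config$n_trials),
    category = ifelse(nogo, "nogo", "go"),
    responded = runif(config$n_trials) < p_resp
  )
}
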