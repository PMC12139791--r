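# Helper: connectome list with a planted separable mean shift between
# conditions on a subset of edges.
make_paired_conns <- function(n_sub, n_nodes, shift, sd = 0.1, seed = 1) {
  set.seed(seed)
  ut <- which(upper.tri(diag(n_nodes)))
  planted <- sample(ut, max(3, length(ut) %/% 10))
  conns <- list()
  for (s in seq_len(n_sub)) {
    for (cond in c("MA", "PL")) {
      vals <- matrix(0, n_nodes, n_nodes)
      vals[ut] <- rnorm(length(ut), sd = sd)
      if (cond == "MA") vals[planted] <- vals[planted] + shift
      vals[lower.tri(vals)] <- t(vals)[lower.tri(vals)]
      conns[[paste0("S", s, "_", cond)]] <- conn_matrix(
        vals, meta = list(subject_id = paste0("S", s), condition = cond))
    }
  }
  conns
}

test_that("design matrices have one row per scan and one column per edge", {
  conns <- make_paired_conns(10, 30, shift = 0)
  design <- build_design(conns)
  expect_equal(dim(design$x), c(20, 30 * 29 / 2))
  expect_equal(levels(design$y), c("MA", "PL"))
  expect_equal(length(unique(design$subject)), 10)
})

test_that("an edge missing in any scan is dropped globally", {
  conns <- make_paired_conns(5, 30, shift = 0)
  v <- conns[[3]]$values
  v[1, 2] <- v[2, 1] <- NaN
  conns[[3]] <- conn_matrix(v, valid_nodes = rep(TRUE, 30),
                            meta = conns[[3]]$meta)
  expect_message(design <- build_design(conns), "dropping 1 edge")
  expect_equal(ncol(design$x), 435 - 1)
})

test_that("vectorise-then-devectorise returns the original edge values", {
  set.seed(81)
  vals <- random_symmetric(12)
  conn <- conn_matrix(vals, meta = list(subject_id = "a", condition = "MA"))
  conn2 <- conn_matrix(-vals, meta = list(subject_id = "a", condition = "PL"))
  design <- build_design(list(conn, conn2))
  w <- design$x[1, ]
  back <- cpmshift:::devectorize_weights(w, design$edge_index, 12)
  expect_equal(back, vals, tolerance = 1e-12)
  expect_equal(back, t(back))
})

test_that("a strongly separable planted effect is classified perfectly", {
  conns <- make_paired_conns(8, 20, shift = 2, sd = 0.05, seed = 82)
  report <- loso_paired_cv(build_design(conns))
  expect_equal(report$accuracy, 1)
  expect_equal(nrow(report$predictions), 16)
  expect_equal(report$mean_weights, t(report$mean_weights))
})

test_that("the mean weight map points the planted direction", {
  conns <- make_paired_conns(10, 20, shift = 1.5, sd = 0.05, seed = 83)
  report <- loso_paired_cv(build_design(conns))
  # planted edges carry higher values under MA; their weights must be the
  # most positive ones
  set.seed(83)
  ut <- which(upper.tri(diag(20)))
  planted <- sample(ut, max(3, length(ut) %/% 10))
  w_planted <- mean(report$mean_weights[planted])
  w_rest <- mean(report$mean_weights[setdiff(ut, planted)])
  expect_gt(w_planted, w_rest)
  expect_gt(w_planted, 0)
})

test_that("single-scan subjects are held out and predicted alone", {
  conns <- make_paired_conns(6, 20, shift = 2, sd = 0.05, seed = 84)
  conns[["S3_PL"]] <- NULL  # subject 3 has only the MA scan
  report <- loso_paired_cv(build_design(conns))
  expect_equal(nrow(report$predictions), 11)
  expect_equal(sum(report$predictions$subject == "S3"), 1)
})

test_that("a fold whose training set is single-class errors out", {
  conns <- make_paired_conns(3, 20, shift = 1, seed = 85)
  # subjects 2 and 3 keep only MA scans: when subject 1 is held out the
  # training set has one class
  conns[["S2_PL"]] <- NULL
  conns[["S3_PL"]] <- NULL
  expect_error(loso_paired_cv(build_design(conns)), "single class")
})

test_that("cross-validation is deterministic and needs 3+ subjects", {
  conns <- make_paired_conns(6, 16, shift = 0.3, seed = 86)
  design <- build_design(conns)
  r1 <- loso_paired_cv(design)
  r2 <- loso_paired_cv(design)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$mean_weights, r2$mean_weights)
  expect_error(loso_paired_cv(build_design(make_paired_conns(2, 16, 0, seed = 1))),
               "at least 3")
})

test_that("permutation p has the add-one floor under a strong effect", {
  conns <- make_paired_conns(8, 16, shift = 2, sd = 0.05, seed = 87)
  design <- build_design(conns)
  pt <- permutation_test(design, n_perm = 100, seed = 3)
  expect_equal(pt$observed, 1)
  expect_gte(pt$perm_p, 1 / 101)
  expect_lt(pt$perm_p, 0.05)
  # identical seed reproduces the identical null
  pt2 <- permutation_test(design, n_perm = 100, seed = 3)
  expect_identical(pt$null_accuracies, pt2$null_accuracies)
})

test_that("an observed accuracy below the null median gives a large p", {
  conns <- make_paired_conns(8, 16, shift = 0, seed = 88)
  design <- build_design(conns)
  pt <- permutation_test(design, n_perm = 50, seed = 4, observed = 0)
  expect_gt(pt$perm_p, 0.5)
})

test_that("the full-reshuffle scheme is available and valid", {
  conns <- make_paired_conns(6, 16, shift = 2, sd = 0.05, seed = 89)
  design <- build_design(conns)
  pt <- permutation_test(design, n_perm = 30, seed = 5, scheme = "full")
  expect_length(pt$null_accuracies, 30)
  expect_lte(pt$perm_p, 1)
  expect_error(permutation_test(design, n_perm = 0), "n_perm")
})

test_that("absolute-rule selection reproduces threshold counts exactly", {
  # a synthetic 268-node weight map with known counts beyond the published
  # thresholds 0.0020 / -0.0023
  set.seed(90)
  n <- 268
  ut <- which(upper.tri(diag(n)))
  w <- rep(0, length(ut))
  pos_idx <- sample(seq_along(w), 135)
  neg_idx <- sample(setdiff(seq_along(w), pos_idx), 168)
  w[pos_idx] <- runif(135, 0.0021, 0.01)
  w[neg_idx] <- runif(168, -0.01, -0.0024)
  others <- setdiff(seq_along(w), c(pos_idx, neg_idx))
  w[others] <- runif(length(others), -0.0020, 0.0019)
  wm <- matrix(0, n, n)
  wm[ut] <- w
  wm[lower.tri(wm)] <- t(wm)[lower.tri(wm)]
  sel <- select_edges(wm, rule = "absolute",
                      pos_threshold = 0.0020, neg_threshold = -0.0023)
  expect_equal(sel$n_positive, 135)
  expect_equal(sel$n_negative, 168)
  expect_equal(sel$positive_mask$edge_count, 135)
  expect_equal(overlap_count(sel$positive_mask, sel$negative_mask), 0)
})

test_that("percentile selection takes floor(q% of finite edges) per side", {
  set.seed(91)
  n <- 268
  ut <- which(upper.tri(diag(n)))
  wm <- matrix(0, n, n)
  wm[ut] <- rnorm(length(ut))
  wm[lower.tri(wm)] <- t(wm)[lower.tri(wm)]
  sel <- select_edges(wm, rule = "percentile", q = 2.5)
  expect_equal(sel$n_positive, floor(0.025 * 35778))  # 894
  expect_equal(sel$n_negative, 894)
  # selected edges sit beyond the implied thresholds
  expect_gt(min(wm[sel$positive_mask$matrix == 1]), sel$neg_threshold)
})

test_that("an all-zero weight map selects nothing", {
  wm <- matrix(0, 20, 20)
  expect_warning(sel <- select_edges(wm, rule = "absolute",
                                     pos_threshold = 0.1,
                                     neg_threshold = -0.1),
                 "empty")
  expect_equal(sel$n_positive, 0)
  expect_equal(sel$n_negative, 0)
})

test_that("classification accuracy rises with the planted effect size", {
  accs <- sapply(c(0, 0.06, 0.2), function(e) {
    mean(sapply(1:6, function(r) {
      cfg <- synth_config(n_subjects = 10, n_nodes = 20, effect_size = e,
                          n_timepoints = 60, seed = 300 * r + round(1000 * e))
      d <- gen_condition_dataset(cfg)
      qc <- qc_filter(d$manifest)
      inc <- qc[qc$included & qc$run_type == "rest", ]
      conns <- lapply(seq_len(nrow(inc)), function(i)
        compute_fc(d$timeseries[[inc$path[i]]],
                   meta = list(subject_id = inc$subject_id[i],
                               condition = inc$condition[i])))
      loso_paired_cv(build_design(conns), keep_weights = FALSE)$accuracy
    }))
  })
  expect_true(all(diff(accs) >= 0) || (accs[3] > accs[1] && accs[3] > 0.8))
  expect_gt(accs[3], accs[1])
})
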