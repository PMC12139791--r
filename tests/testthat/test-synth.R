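test_that("generated masks hit requested edge counts at full atlas scale", {
  cfg <- synth_config(n_nodes = 268, seed = 7,
                      mask_sizes = c(high_attention = 757, low_attention = 630))
  masks <- gen_masks(cfg)
  expect_equal(masks$high_attention$edge_count, 757)
  expect_equal(masks$low_attention$edge_count, 630)
  expect_equal(overlap_count(masks$high_attention, masks$low_attention), 0)
})

test_that("mask generation is deterministic, supports overlap and empty masks", {
  cfg <- synth_config(n_nodes = 30, seed = 11)
  m1 <- gen_masks(cfg)
  m2 <- gen_masks(cfg)
  expect_identical(m1, m2)

  cfg_overlap <- synth_config(n_nodes = 30, mask_overlap = 4, seed = 11,
                              mask_sizes = c(high_attention = 20,
                                             low_attention = 15))
  mo <- gen_masks(cfg_overlap)
  expect_equal(overlap_count(mo$high_attention, mo$low_attention), 4)

  cfg_empty <- synth_config(n_nodes = 20, seed = 3,
                            mask_sizes = c(high_attention = 5,
                                           low_attention = 5, extra = 0))
  expect_equal(gen_masks(cfg_empty)$extra$edge_count, 0)

  cfg_bad <- synth_config(n_nodes = 8, seed = 1,
                          mask_sizes = c(high_attention = 100))
  expect_error(gen_masks(cfg_bad), "exceeds")
})

test_that("default mask sizes scale with the possible-edge count", {
  cfg <- synth_config(n_nodes = 268)
  expect_equal(unname(cfg$mask_sizes[c("high_attention", "low_attention",
                                       "arousal_pos", "arousal_neg")]),
               c(757, 630, 469, 555))
  cfg40 <- synth_config(n_nodes = 40)
  expect_equal(unname(cfg40$mask_sizes["high_attention"]),
               round(757 * total_edges(40) / 35778))
})

test_that("dataset generation is byte-identical under a fixed seed", {
  cfg <- synth_config(n_subjects = 4, n_nodes = 20, n_timepoints = 40, seed = 13)
  d1 <- gen_condition_dataset(cfg)
  d2 <- gen_condition_dataset(cfg)
  expect_identical(d1$timeseries, d2$timeseries)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$subject_effect, d2$subject_effect)
  # and a different seed changes the draw
  d3 <- gen_condition_dataset(synth_config(n_subjects = 4, n_nodes = 20,
                                           n_timepoints = 40, seed = 14))
  expect_false(identical(d1$timeseries, d3$timeseries))
})

test_that("the generated manifest parses back with zero exclusions by default", {
  cfg <- synth_config(n_subjects = 5, n_nodes = 20, n_timepoints = 40, seed = 15)
  d <- gen_condition_dataset(cfg)
  dir <- withr::local_tempdir()
  write_condition_dataset(d, dir)
  man <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 10)
  dec <- qc_filter(man)
  expect_true(all(dec$included))
  # time series files round-trip
  ts <- read_delim <- as.matrix(read.table(file.path(dir, man$path[1]), sep = "\t"))
  expect_equal(unname(ts), d$timeseries[[sub(".tsv", "", basename(man$path[1]))]],
               tolerance = 0, ignore_attr = TRUE)
})

test_that("planted QC failures appear at the configured rate", {
  cfg <- synth_config(n_subjects = 25, n_nodes = 20, n_timepoints = 40,
                      qc_fail_frac = 0.2, seed = 16)
  d <- gen_condition_dataset(cfg)  # 50 runs
  dec <- qc_filter(d$manifest)
  n_fail <- sum(!dec$included)
  # binomial(50, 0.2): central 99.9% envelope
  expect_gte(n_fail, qbinom(0.0005, 50, 0.2))
  expect_lte(n_fail, qbinom(0.9995, 50, 0.2))
})

test_that("with no planted effect the condition contrast is null", {
  set.seed(17)
  tstats <- sapply(1:8, function(r) {
    cfg <- synth_config(n_subjects = 15, n_nodes = 20, n_timepoints = 60,
                        effect_size = 0, seed = 400 + r)
    d <- gen_condition_dataset(cfg)
    diffs <- sapply(sprintf("S%03d", 1:15), function(s) {
      z <- function(cond) attention_strength(
        compute_fc(d$timeseries[[paste(s, cond, "rest", sep = "_")]]),
        d$masks$high_attention, d$masks$low_attention)$diff
      z("MA") - z("PL")
    })
    paired_t(diffs)$t
  })
  expect_lt(abs(mean(tstats)), 1.5)
  expect_lt(max(abs(tstats)), 5)
})

test_that("the estimated condition difference grows with the planted effect", {
  mean_delta <- sapply(c(0.03, 0.08, 0.16), function(e) {
    mean(sapply(1:10, function(r) {
      cfg <- synth_config(n_subjects = 8, n_nodes = 20, n_timepoints = 60,
                          effect_size = e, heterogeneity = 0.3,
                          seed = 600 + 37 * r)
      d <- gen_condition_dataset(cfg)
      mean(sapply(sprintf("S%03d", 1:8), function(s) {
        z <- function(cond) attention_strength(
          compute_fc(d$timeseries[[paste(s, cond, "rest", sep = "_")]]),
          d$masks$high_attention, d$masks$low_attention)$diff
        z("MA") - z("PL")
      }))
    }))
  })
  expect_true(all(diff(mean_delta) > 0))
})

test_that("subject multipliers are shared across run types", {
  cfg <- synth_config(n_subjects = 10, n_nodes = 20, n_timepoints = 80,
                      run_types = c("rest", "doors1"), seed = 18)
  d <- gen_condition_dataset(cfg)
  expect_equal(length(d$timeseries), 10 * 2 * 2)
  delta <- function(rt) {
    sapply(sprintf("S%03d", 1:10), function(s) {
      z <- function(cond) attention_strength(
        compute_fc(d$timeseries[[paste(s, cond, rt, sep = "_")]]),
        d$masks$high_attention, d$masks$low_attention)$diff
      z("MA") - z("PL")
    })
  }
  r <- consistency_corr(delta("rest"), delta("doors1"))
  expect_gt(r$r, 0.4)  # shared latent effect induces cross-context consistency
})

test_that("go/no-go generation respects trial mix and the detection model", {
  cfg <- gradcpt_config(seed = 19)
  trials <- gen_gradcpt(cfg)
  expect_equal(nrow(trials), 750)
  n_nogo <- sum(trials$category == "nogo")
  expect_gte(n_nogo, qbinom(0.0005, 750, 0.1))
  expect_lte(n_nogo, qbinom(0.9995, 750, 0.1))
  expect_identical(gen_gradcpt(cfg), trials)  # determinism

  # null observer: recovered d' near zero. At 675/75 go/no-go trials the
  # delta-method sd of the null d' is ~0.15, so |d'| < 0.3 covers ~95%.
  set.seed(20)
  d0 <- sapply(1:40, function(r) {
    score_gradcpt(gen_gradcpt(gradcpt_config(d_true = 0, criterion = 0,
                                             seed = 700 + r)))$dprime
  })
  expect_lt(abs(mean(d0)), 0.1)
  expect_gt(mean(abs(d0) < 0.3), 0.9)

  # biased observer: both rates drop, d' preserved in expectation
  db <- mean(sapply(1:40, function(r) {
    score_gradcpt(gen_gradcpt(gradcpt_config(d_true = 1.5, criterion = 0.5,
                                             seed = 800 + r)))$dprime
  }))
  expect_equal(db, 1.5, tolerance = 0.15)
})
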