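test_that("two-sample KS matches the EDF sup-distance and its edge cases", {
  x <- c(0.1, 0.2, 0.3)
  y <- c(0.15, 0.25, 0.35)
  p <- two_sample_ks(x, y)
  expect_equal(attr(p, "statistic"), 1 / 3)
  expect_equal(attr(p, "statistic"), edf_sup_distance(x, y))

  # identical samples: zero statistic, p = 1
  p <- two_sample_ks(x, x)
  expect_equal(attr(p, "statistic"), 0)
  expect_equal(as.numeric(p), 1)

  # disjoint supports force the maximal statistic
  z <- withr::with_seed(1, rnorm(50))
  p <- two_sample_ks(z, z + 10)
  expect_equal(attr(p, "statistic"), 1)
  expect_lt(as.numeric(p), 1e-6)

  expect_error(two_sample_ks(1, y), class = "mdgnet_input_error")
})

test_that("KS statistic agrees with the EDF oracle on random samples", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      x <- rnorm(sample(5:30, 1))
      y <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
    })
    expect_equal(attr(two_sample_ks(x, y), "statistic"),
                 edf_sup_distance(x, y))
  }
})

test_that("normality check is calibrated under normal data and rejects gross shapes", {
  cover <- power <- logical(100)
  for (i in 1:100) {
    withr::with_seed(i, {
      good <- rnorm(500, mean = 5, sd = 2)
      bad <- sample(c(-1, 1), 500, replace = TRUE)
    })
    cover[i] <- as.numeric(normality_ks(good)) > 0.001
    power[i] <- as.numeric(normality_ks(bad)) < 0.001
  }
  expect_gte(mean(cover), 0.95)
  expect_gte(mean(power), 0.95)
  # constant sample is a degenerate, non-normal signal
  expect_equal(as.numeric(normality_ks(rep(2, 10))), 0)
})

test_that("variance-ratio test is two-sided, symmetric, and matches the closed form", {
  x <- withr::with_seed(1, rnorm(12))
  expect_equal(as.numeric(variance_f_test(x, x)), 1)

  y <- withr::with_seed(2, rnorm(15, sd = 3))
  expect_equal(as.numeric(variance_f_test(x, y)),
               as.numeric(variance_f_test(y, x)))

  # samples scaled to sample variances exactly 1 and 16 (n = 10 each):
  # two-sided p is 2 P(F_{9,9} >= 16)
  a <- withr::with_seed(3, as.numeric(scale(rnorm(10))))
  b <- withr::with_seed(4, as.numeric(scale(rnorm(10))) * 4)
  expect_equal(var(a), 1)
  expect_equal(var(b), 16)
  expect_equal(as.numeric(variance_f_test(a, b)),
               2 * (1 - pf(16, 9, 9)))

  expect_error(variance_f_test(rep(1, 5), x), class = "mdgnet_degenerate_error")
})

test_that("location tests: zero effect, exact Mann-Whitney, t/Welch agreement", {
  x <- withr::with_seed(5, rnorm(10))
  for (route in c("t", "welch", "mann_whitney")) {
    expect_equal(as.numeric(location_test(x, x, route)), 1, tolerance = 1e-8)
  }
  # all-tied convention
  expect_equal(as.numeric(location_test(rep(3, 4), rep(3, 5), "t")), 1)

  # exact Mann-Whitney: 2/20 rank assignments at least as extreme
  expect_equal(as.numeric(location_test(1:3, 4:6, "mann_whitney")), 0.1)

  # equal n and equal variance: Satterthwaite df reduces to pooled df
  y <- withr::with_seed(6, rnorm(10, mean = 0.4))
  expect_equal(as.numeric(location_test(x, y, "t")),
               as.numeric(location_test(x, y, "welch")),
               tolerance = 0.02)
})

test_that("exact Mann-Whitney matches full rank-assignment enumeration for n <= 5", {
  for (seed in 1:12) {
    withr::with_seed(seed, {
      n <- sample(2:5, 1)
      m <- sample(2:5, 1)
      x <- round(rnorm(n), 6)
      y <- round(rnorm(m, mean = runif(1, -2, 2)), 6)
    })
    expect_equal(as.numeric(location_test(x, y, "mann_whitney")),
                 mw_enum_p(x, y), tolerance = 1e-12,
                 info = paste("seed", seed))
  }
})

test_that("Benjamini-Hochberg adjustment matches the hand step-up and inflates", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  p <- withr::with_seed(7, runif(50))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "mdgnet_input_error")
})

test_that("the cascade routes every gene exactly once and null genes pass through", {
  ds <- gen_de_dataset(sim_config(n_genes = 80, n_samples_c = 20,
                                  n_samples_e = 20, seed = 21))
  scr <- screen_genes(ds$control, ds$experimental)
  rec <- tidy(scr)
  expect_equal(nrow(rec), 80)
  expect_true(all(rec$route %in% c("ks2_different", "t", "welch",
                                   "mann_whitney")))
  expect_equal(sum(table(rec$route)), 80)
  # a gene identical in both cohorts is unflagged with p near 1
  ctrl <- ds$control
  expt <- ds$experimental
  expt[1, -1] <- as.list(unname(unlist(ctrl[1, 2:21])))
  scr2 <- screen_genes(ctrl, expt)
  expect_false(tidy(scr2)$flagged[1])
  expect_gt(tidy(scr2)$p_loc[1], 0.95)
})

test_that("routes at zero effect follow the planted branch design", {
  ds <- gen_de_dataset(sim_config(
    n_genes = 300, n_samples_c = 100, n_samples_e = 100, effect_size = 0,
    de_blocks = c(mean_shift = 40, var_mean_shift = 40), seed = 22))
  scr <- screen_genes(ds$control, ds$experimental)
  rec <- dplyr::left_join(tidy(scr), ds$truth_de, by = "gene_id")
  b <- rec[rec$branch == "mean_shift", ]
  expect_gte(mean(b$route == "t"), 0.9)
  cc <- rec[rec$branch == "var_mean_shift", ]
  expect_gte(mean(cc$route == "welch"), 0.9)
  # none flagged: every branch is location-null at delta = 0
  expect_lte(sum(rec$flagged), 2)
})

test_that("the heavy-tailed branch reaches Mann-Whitney once normality has power", {
  ds <- gen_de_dataset(sim_config(
    n_genes = 200, n_samples_c = 400, n_samples_e = 400, effect_size = 0,
    de_blocks = c(heavy_tail = 50), seed = 23))
  scr <- screen_genes(ds$control, ds$experimental, normality = "lilliefors")
  rec <- dplyr::left_join(tidy(scr), ds$truth_de, by = "gene_id")
  expect_gte(mean(rec$route[rec$branch == "heavy_tail"] == "mann_whitney"),
             0.9)
})

test_that("shape-shifted genes exit at the two-sample KS stage at large n", {
  ds <- gen_de_dataset(sim_config(
    n_genes = 200, n_samples_c = 300, n_samples_e = 300,
    de_blocks = c(shape_shift = 40), seed = 24))
  scr <- screen_genes(ds$control, ds$experimental)
  rec <- dplyr::left_join(tidy(scr), ds$truth_de, by = "gene_id")
  expect_gte(mean(rec$route[rec$branch == "shape_shift"] == "ks2_different"),
             0.9)
})

test_that("loosening any cutoff never shrinks the flagged set", {
  ds <- gen_de_dataset(sim_config(
    n_genes = 150, n_samples_c = 40, n_samples_e = 40, effect_size = 1,
    de_blocks = c(mean_shift = 30, var_mean_shift = 20, heavy_tail = 20),
    seed = 25))
  scales <- c(1, 20, 400)
  flagged <- lapply(scales, function(s) {
    cuts <- cascade_cutoffs(q_ks2 = min(0.9, 5e-4 * s),
                            q_norm = min(0.9, 1e-3 * s),
                            q_f = min(0.9, 1e-3 * s),
                            q_loc = min(0.9, 1e-3 * s))
    flagged_genes(screen_genes(ds$control, ds$experimental, cuts))
  })
  expect_true(all(flagged[[1]] %in% flagged[[2]]))
  expect_true(all(flagged[[2]] %in% flagged[[3]]))
})

test_that("staged and global FDR scopes agree on strong signals", {
  ds <- gen_de_dataset(sim_config(
    n_genes = 120, n_samples_c = 50, n_samples_e = 50,
    de_blocks = c(mean_shift = 20), seed = 26))
  s1 <- screen_genes(ds$control, ds$experimental, fdr_scope = "staged")
  s2 <- screen_genes(ds$control, ds$experimental, fdr_scope = "global")
  truth <- ds$truth_de$gene_id[ds$truth_de$differential]
  expect_true(all(truth %in% flagged_genes(s1)))
  expect_true(all(truth %in% flagged_genes(s2)))
})

test_that("zero-variance genes are routed to Mann-Whitney, not the parametric branch", {
  ctrl <- fixture_expr(10, 12, seed = 31)
  expt <- fixture_expr(10, 12, seed = 32)
  # constant in both cohorts: the two-sample KS passes, normality cannot hold
  ctrl[3, -1] <- as.list(rep(5, 12))
  expt[3, -1] <- as.list(rep(5, 12))
  scr <- screen_genes(ctrl, expt)
  rec <- tidy(scr)
  expect_equal(rec$route[3], "mann_whitney")
  expect_false(rec$flagged[3])
})

test_that("screen rejects misaligned cohorts", {
  a <- fixture_expr(5, 10, seed = 33)
  b <- fixture_expr(5, 10, seed = 34)
  b$gene_id <- rev(b$gene_id)
  expect_error(screen_genes(a, b), class = "mdgnet_alignment_error")
})
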