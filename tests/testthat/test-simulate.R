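test_that("null pair has the requested shape, distribution and determinism", {
  pair <- gen_null_pair(244, 64, 82, seed = 1)
  expect_equal(dim(as_expr_matrix(pair$control)), c(244, 64))
  expect_equal(dim(as_expr_matrix(pair$experimental)), c(244, 82))
  pair2 <- gen_null_pair(244, 64, 82, seed = 1)
  expect_identical(pair, pair2)
  expect_error(gen_null_pair(0, 5, 5, seed = 1), class = "mdgnet_input_error")

  # per-gene means sit near 0 at the Monte Carlo scale of the draw
  small <- gen_null_pair(10, 5, 5, seed = 7)
  means <- rowMeans(as_expr_matrix(small$control))
  expect_gte(sum(abs(means) <= 3 / sqrt(5)), 9)
})

test_that("sim_config validates counts, blocks and module loadings", {
  expect_error(sim_config(n_genes = 10, de_blocks = c(mean_shift = 20)),
               class = "mdgnet_config_error")
  expect_error(sim_config(de_blocks = c(bogus = 5)),
               class = "mdgnet_config_error")
  expect_error(
    sim_config(module_spec = list(list(size = 10, rho_c = 1.2, rho_e = 0.1,
                                       n_planted = 2))),
    class = "mdgnet_config_error")
  expect_error(
    sim_config(module_spec = list(list(size = 10, rho_c = 0.3, rho_e = 0.8,
                                       n_planted = 2))),
    class = "mdgnet_config_error")
})

test_that("identical configs generate identical datasets", {
  cfg <- sim_config(n_genes = 50, n_samples_c = 10, n_samples_e = 12,
                    de_blocks = c(shape_shift = 5, heavy_tail = 5), seed = 9)
  expect_identical(gen_de_dataset(cfg), gen_de_dataset(cfg))
  cfg2 <- sim_config(n_genes = 40, n_samples_c = 10, n_samples_e = 10,
                     seed = 9,
                     module_spec = list(list(size = 10, rho_c = 0.8,
                                             rho_e = 0.2, n_planted = 2)))
  expect_identical(gen_connectivity_dataset(cfg2),
                   gen_connectivity_dataset(cfg2))
})

test_that("zero effect size marks location branches as null-equivalent", {
  cfg <- sim_config(n_genes = 40, n_samples_c = 10, n_samples_e = 10,
                    effect_size = 0, seed = 2,
                    de_blocks = c(shape_shift = 5, mean_shift = 5,
                                  var_mean_shift = 5, heavy_tail = 5))
  truth <- gen_de_dataset(cfg)$truth_de
  expect_true(all(truth$differential[truth$branch == "shape_shift"]))
  expect_false(any(truth$differential[truth$branch != "shape_shift"]))
})

test_that("planted branch moments match their design", {
  cfg <- sim_config(n_genes = 40, n_samples_c = 4000, n_samples_e = 4000,
                    effect_size = 2, seed = 3,
                    de_blocks = c(shape_shift = 10, mean_shift = 10,
                                  var_mean_shift = 10, heavy_tail = 10))
  ds <- gen_de_dataset(cfg)
  mc <- as_expr_matrix(ds$control)
  me <- as_expr_matrix(ds$experimental)
  br <- ds$truth_de$branch
  # shape branch: same first two moments, different shape
  i <- which(br == "shape_shift")
  expect_equal(mean(me[i, ]), 0, tolerance = 0.05)
  expect_equal(sd(me[i, ]), 1, tolerance = 0.05)
  # mean-shift branch: shift = effect size, equal variance
  i <- which(br == "mean_shift")
  expect_equal(mean(me[i, ]) - mean(mc[i, ]), 2, tolerance = 0.05)
  # unequal-variance branch: variance ratio 4
  i <- which(br == "var_mean_shift")
  expect_equal(var(as.vector(me[i, ])) / var(as.vector(mc[i, ])), 4,
               tolerance = 0.2)
  # heavy-tailed branch: unit variance, excess kurtosis
  i <- which(br == "heavy_tail")
  z <- as.vector(mc[i, ])
  expect_equal(var(z), 1, tolerance = 0.15)
  expect_gt(mean(((z - mean(z)) / sd(z))^4), 4)
})

test_that("null-only screening keeps the flagged fraction within the staged cutoffs", {
  frac <- vapply(1:50, function(seed) {
    cfg <- sim_config(n_genes = 100, n_samples_c = 25, n_samples_e = 25,
                      seed = seed)
    ds <- gen_de_dataset(cfg)
    length(flagged_genes(screen_genes(ds$control, ds$experimental))) / 100
  }, 0)
  expect_lte(mean(frac), 5 * 0.001)
})

test_that("a 3-sigma mean shift is flagged for nearly all planted genes", {
  hits <- total <- 0
  for (seed in 1:50) {
    cfg <- sim_config(n_genes = 100, n_samples_c = 60, n_samples_e = 60,
                      de_blocks = c(mean_shift = 20), effect_size = 3,
                      seed = seed)
    ds <- gen_de_dataset(cfg)
    scr <- screen_genes(ds$control, ds$experimental)
    truth <- ds$truth_de$gene_id[ds$truth_de$branch == "mean_shift"]
    hits <- hits + sum(truth %in% flagged_genes(scr))
    total <- total + length(truth)
  }
  expect_gte(hits / total, 0.95)
})

test_that("recovery power is monotone in the planted effect", {
  flag_rate <- function(delta) {
    mean(vapply(1:20, function(seed) {
      cfg <- sim_config(n_genes = 60, n_samples_c = 40, n_samples_e = 40,
                        de_blocks = c(mean_shift = 15), effect_size = delta,
                        seed = seed)
      ds <- gen_de_dataset(cfg)
      truth <- ds$truth_de$gene_id[ds$truth_de$branch == "mean_shift"]
      mean(truth %in% flagged_genes(screen_genes(ds$control,
                                                 ds$experimental)))
    }, 0))
  }
  rates <- vapply(c(0.5, 1.5, 3), flag_rate, 0)
  expect_true(all(diff(rates) >= 0))

  mdg_rate <- function(rho_e) {
    mean(vapply(1:20, function(seed) {
      cfg <- sim_config(n_genes = 120, n_samples_c = 40, n_samples_e = 40,
                        seed = seed,
                        module_spec = list(list(size = 20, rho_c = 0.9,
                                                rho_e = rho_e,
                                                n_planted = 4)))
      ds <- gen_connectivity_dataset(cfg)
      ranking <- md_scores(degree_sweep(ds$control, ds$experimental))
      mean(ds$truth_mdg %in% top_k(ranking, 8))
    }, 0))
  }
  recov <- vapply(c(0.7, 0.4, 0.1), mdg_rate, 0)
  expect_true(all(diff(recov) >= 0))
})

test_that("connectivity generator plants the intended correlation drop", {
  cfg <- sim_config(n_genes = 230, n_samples_c = 60, n_samples_e = 60,
                    seed = 4,
                    module_spec = list(list(size = 30, rho_c = 0.9,
                                            rho_e = 0.1, n_planted = 5)))
  ds <- gen_connectivity_dataset(cfg)
  mc <- as_expr_matrix(ds$control)
  me <- as_expr_matrix(ds$experimental)
  peers <- 6:30  # non-planted module genes
  for (g in seq_len(5)) {
    cor_c <- mean(abs(cor(mc[g, ], t(mc[peers, ]), method = "spearman")))
    cor_e <- mean(abs(cor(me[g, ], t(me[peers, ]), method = "spearman")))
    expect_gt(cor_c, cor_e)
  }
  # equal loadings leave no planted truth
  cfg2 <- sim_config(n_genes = 40, n_samples_c = 10, n_samples_e = 10,
                     seed = 5,
                     module_spec = list(list(size = 10, rho_c = 0.6,
                                             rho_e = 0.6, n_planted = 3)))
  expect_length(gen_connectivity_dataset(cfg2)$truth_mdg, 0)
})

test_that("gene-set generator produces contained, planted, reproducible sets", {
  ids <- sprintf("g%04d", 1:100)
  sets <- gen_gene_sets(ids, 10, c(5, 20), seed = 6)
  expect_length(sets$sets, 10)
  expect_true(all(unlist(sets$sets) %in% ids))

  planted <- ids[11:20]
  sets2 <- gen_gene_sets(ids, 8, c(5, 20), planted_term_genes = planted,
                         seed = 6)
  enr <- enrich(planted, sets2, p_cutoff = 1, min_count = 0, min_factor = 0)
  expect_equal(enr$term[which.min(enr$p)], names(sets2$sets)[1])

  f1 <- tempfile(fileext = ".gmt")
  f2 <- tempfile(fileext = ".gmt")
  write_gmt(gen_gene_sets(ids, 5, c(5, 10), seed = 8), f1)
  write_gmt(gen_gene_sets(ids, 5, c(5, 10), seed = 8), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(gen_gene_sets(character(0), 5), class = "mdgnet_config_error")
  expect_error(gen_gene_sets(ids[1:3], 5, c(5, 10)),
               class = "mdgnet_config_error")
})
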