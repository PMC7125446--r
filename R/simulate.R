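#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generators. Defaults emulate
#' the peripheral-blood case-control design the pipeline targets: two cohorts
#' of 64 (control) and 82 (experimental) samples and a gene panel in the
#' thousands, with a standardized effect size of 3 for the planted
#' differential branches.
#'
#' @param n_genes total number of genes.
#' @param n_samples_c,n_samples_e samples per cohort.
#' @param seed integer seed; all generator randomness flows from it.
#' @param de_blocks named integer vector of planted differential-branch sizes:
#'   `shape_shift` (same mean/variance, different distribution shape, exercises
#'   the two-sample KS exit), `mean_shift` (normal, equal variance, t route),
#'   `var_mean_shift` (normal, unequal variance, Welch route), `heavy_tail`
#'   (standardized heavy-tailed family, location shift, Mann-Whitney route).
#'   All remaining genes are null. Any subset may be given; omitted blocks are 0.
#' @param effect_size standardized location shift delta applied to the
#'   mean-shift, variance-shift and heavy-tail branches.
#' @param var_ratio variance ratio for the `var_mean_shift` branch (>= 1);
#'   the experimental cohort's variance is `var_ratio` times the control's.
#' @param module_spec list of co-expression modules for
#'   [gen_connectivity_dataset()]; each element a list with `size`, `rho_c`
#'   (within-module loading in the control cohort), `rho_e` (loading of the
#'   planted genes in the experimental cohort) and `n_planted`. Loadings must
#'   satisfy `0 <= rho_e <= rho_c < 1`.
#' @return A `sim_config` object (validated list).
#' @examples
#' sim_config(n_genes = 500, de_blocks = c(mean_shift = 50))
#' @export
sim_config <- function(n_genes = 2000, n_samples_c = 64, n_samples_e = 82,
                       seed = 1L,
                       de_blocks = c(shape_shift = 0, mean_shift = 0,
                                     var_mean_shift = 0, heavy_tail = 0),
                       effect_size = 3, var_ratio = 4,
                       module_spec = list()) {
  known <- c("shape_shift", "mean_shift", "var_mean_shift", "heavy_tail")
  if (length(de_blocks)) {
    if (is.null(names(de_blocks)) || !all(names(de_blocks) %in% known)) {
      stop_config(paste0("de_blocks names must be among: ",
                         paste(known, collapse = ", ")))
    }
  }
  blocks <- setNames(rep(0L, length(known)), known)
  blocks[names(de_blocks)] <- as.integer(de_blocks)
  if (any(c(n_genes, n_samples_c, n_samples_e) < 1) || any(blocks < 0)) {
    stop_config("counts must be positive and block sizes non-negative")
  }
  if (sum(blocks) > n_genes) {
    stop_config("differential block sizes exceed n_genes")
  }
  if (var_ratio < 1) stop_config("var_ratio must be >= 1")
  for (m in module_spec) {
    need <- c("size", "rho_c", "rho_e", "n_planted")
    if (!all(need %in% names(m))) {
      stop_config("each module needs size, rho_c, rho_e and n_planted")
    }
    if (m$rho_c < 0 || m$rho_c >= 1 || m$rho_e < 0 || m$rho_e >= 1) {
      stop_config("module loadings must lie in [0, 1)")
    }
    if (m$rho_e > m$rho_c) {
      stop_config("planted modules require rho_e <= rho_c")
    }
    if (m$n_planted < 0 || m$n_planted > m$size) {
      stop_config("n_planted must lie in [0, module size]")
    }
  }
  if (sum(vapply(module_spec, function(m) m$size, 0)) > n_genes) {
    stop_config("module sizes exceed n_genes")
  }
  structure(
    list(n_genes = as.integer(n_genes),
         n_samples_c = as.integer(n_samples_c),
         n_samples_e = as.integer(n_samples_e),
         seed = as.integer(seed),
         de_blocks = blocks,
         effect_size = effect_size,
         var_ratio = var_ratio,
         module_spec = module_spec),
    class = "sim_config"
  )
}

gene_ids_for <- function(n) sprintf("g%04d", seq_len(n))

#' Generate a null pair of expression matrices
#'
#' Every entry is drawn independently from a standard normal; this is the
#' i.i.d. null used to calibrate average-degree separability of random
#' correlation networks.
#'
#' @param n_genes,n_samples_c,n_samples_e dimensions (all >= 2).
#' @param seed integer seed; the same seed reproduces the same pair.
#' @return Named list with `control` and `experimental` expression tibbles.
#' @examples
#' pair <- gen_null_pair(10, 5, 6, seed = 1)
#' dim(as_expr_matrix(pair$control))
#' @export
gen_null_pair <- function(n_genes, n_samples_c, n_samples_e, seed) {
  if (any(c(n_genes, n_samples_c, n_samples_e) < 2)) {
    stop_input("all dimensions must be >= 2")
  }
  ids <- gene_ids_for(n_genes)
  withr::with_seed(as.integer(seed), {
    ctrl <- matrix(rnorm(n_genes * n_samples_c), n_genes)
    expt <- matrix(rnorm(n_genes * n_samples_e), n_genes)
  })
  list(
    control = expr_table(ctrl, ids, sprintf("C%03d", seq_len(n_samples_c))),
    experimental = expr_table(expt, ids, sprintf("E%03d", seq_len(n_samples_e)))
  )
}

# Branch distributions. The shape alternative is a symmetric two-component
# normal mixture with matched first two moments (mu = +/- 0.989, sd = 0.15),
# strongly bimodal so the two-sample KS sees it without a mean or variance
# confound. The heavy-tailed family is a standardized Student t with 3 df
# (variance rescaled to 1): same shape in both cohorts, so the two-sample KS
# passes under a pure location shift while normality fails at large n.
.mix_sd <- 0.15
.mix_mu <- sqrt(1 - .mix_sd^2)

rshape <- function(n) {
  comp <- sample(c(-1, 1), n, replace = TRUE)
  rnorm(n, mean = comp * .mix_mu, sd = .mix_sd)
}

rheavy <- function(n, shift = 0) rt(n, df = 3) / sqrt(3) + shift

#' Generate a labeled differential-expression dataset
#'
#' Plants genes that exercise every branch of the screening cascade:
#' shape-shifted genes (control normal, experimental a moment-matched bimodal
#' mixture), equal-variance mean shifts, unequal-variance mean shifts
#' (variance ratio `var_ratio`), heavy-tailed location shifts, and null genes.
#'
#' @param config a [sim_config()].
#' @return A `labeled_dataset`: list with `control` and `experimental`
#'   expression tibbles, `truth_de` (tibble of `gene_id`, `branch`,
#'   `differential`), `truth_mdg` (empty here) and the `config`.
#'   `differential` is `TRUE` for shape-shift genes always and for the three
#'   location branches only when `effect_size != 0`.
#' @examples
#' ds <- gen_de_dataset(sim_config(n_genes = 100, n_samples_c = 20,
#'                                 n_samples_e = 20,
#'                                 de_blocks = c(mean_shift = 10)))
#' table(ds$truth_de$branch)
#' @export
gen_de_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  nc <- config$n_samples_c
  ne <- config$n_samples_e
  d <- config$effect_size
  blocks <- config$de_blocks
  branch <- rep("null", n)
  idx <- 0L
  for (b in names(blocks)) {
    if (blocks[[b]] > 0) {
      branch[idx + seq_len(blocks[[b]])] <- b
      idx <- idx + blocks[[b]]
    }
  }
  ids <- gene_ids_for(n)
  withr::with_seed(config$seed, {
    ctrl <- matrix(rnorm(n * nc), n)
    expt <- matrix(rnorm(n * ne), n)
    for (i in which(branch == "shape_shift")) expt[i, ] <- rshape(ne)
    for (i in which(branch == "mean_shift")) expt[i, ] <- rnorm(ne, mean = d)
    for (i in which(branch == "var_mean_shift")) {
      expt[i, ] <- rnorm(ne, mean = d, sd = sqrt(config$var_ratio))
    }
    for (i in which(branch == "heavy_tail")) {
      ctrl[i, ] <- rheavy(nc)
      expt[i, ] <- rheavy(ne, shift = d)
    }
  })
  truth <- tibble(
    gene_id = ids, branch = branch,
    differential = branch == "shape_shift" |
      (branch %in% c("mean_shift", "var_mean_shift", "heavy_tail") & d != 0)
  )
  structure(
    list(control = expr_table(ctrl, ids, sprintf("C%03d", seq_len(nc))),
         experimental = expr_table(expt, ids, sprintf("E%03d", seq_len(ne))),
         truth_de = truth, truth_mdg = character(0), config = config),
    class = "labeled_dataset"
  )
}

#' Generate a dataset with planted connectivity changes
#'
#' Module genes follow a single-factor model `x = lambda * f + sqrt(1 -
#' lambda^2) * e` with a factor `f` shared per sample. Planted genes load with
#' `rho_c` in the control cohort but only `rho_e` in the experimental cohort,
#' so their correlation to module peers — and hence their network degree —
#' drops between cohorts while their marginal distribution is unchanged.
#' Non-planted module genes load with `rho_c` in both cohorts; background
#' genes are independent noise.
#'
#' @param config a [sim_config()] with a non-empty `module_spec`.
#' @return A `labeled_dataset` whose `truth_mdg` holds the planted gene ids.
#' @examples
#' cfg <- sim_config(n_genes = 60, n_samples_c = 30, n_samples_e = 30,
#'                   module_spec = list(list(size = 20, rho_c = 0.9,
#'                                           rho_e = 0.1, n_planted = 4)))
#' gen_connectivity_dataset(cfg)$truth_mdg
#' @export
gen_connectivity_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!length(config$module_spec)) {
    stop_config("gen_connectivity_dataset needs at least one module in module_spec")
  }
  n <- config$n_genes
  nc <- config$n_samples_c
  ne <- config$n_samples_e
  ids <- gene_ids_for(n)
  planted <- character(0)
  withr::with_seed(config$seed, {
    ctrl <- matrix(rnorm(n * nc), n)
    expt <- matrix(rnorm(n * ne), n)
    idx <- 0L
    for (m in config$module_spec) {
      rows <- idx + seq_len(m$size)
      idx <- idx + m$size
      f_c <- rnorm(nc)
      f_e <- rnorm(ne)
      lam_c <- rep(m$rho_c, m$size)
      lam_e <- rep(m$rho_c, m$size)
      if (m$n_planted > 0) {
        lam_e[seq_len(m$n_planted)] <- m$rho_e
        if (m$rho_e < m$rho_c) {
          planted <- c(planted, ids[rows[seq_len(m$n_planted)]])
        }
      }
      ctrl[rows, ] <- lam_c * matrix(f_c, m$size, nc, byrow = TRUE) +
        sqrt(1 - lam_c^2) * ctrl[rows, , drop = FALSE]
      expt[rows, ] <- lam_e * matrix(f_e, m$size, ne, byrow = TRUE) +
        sqrt(1 - lam_e^2) * expt[rows, , drop = FALSE]
    }
  })
  structure(
    list(control = expr_table(ctrl, ids, sprintf("C%03d", seq_len(nc))),
         experimental = expr_table(expt, ids, sprintf("E%03d", seq_len(ne))),
         truth_de = tibble(gene_id = ids, branch = "null", differential = FALSE),
         truth_mdg = planted, config = config),
    class = "labeled_dataset"
  )
}

#' Generate a synthetic gene-set collection
#'
#' Produces GMT-compatible gene sets over a gene universe, with an optional
#' deliberately enriched term: when `planted_term_genes` is given, the first
#' term is exactly that gene set.
#'
#' @param gene_ids character universe of gene identifiers (non-empty).
#' @param n_terms number of terms.
#' @param term_size_range integer length-2 range of term sizes.
#' @param planted_term_genes optional character vector (subset of `gene_ids`)
#'   forming the planted term.
#' @param seed integer seed.
#' @return A [gene_set_collection()] whose universe is `gene_ids`.
#' @export
gen_gene_sets <- function(gene_ids, n_terms, term_size_range = c(5, 50),
                          planted_term_genes = NULL, seed = 1L) {
  if (!length(gene_ids)) stop_config("empty gene universe")
  if (max(term_size_range) > length(gene_ids)) {
    stop_config("term sizes exceed the number of genes")
  }
  if (!is.null(planted_term_genes) && !all(planted_term_genes %in% gene_ids)) {
    stop_config("planted_term_genes must be a subset of gene_ids")
  }
  withr::with_seed(as.integer(seed), {
    sets <- lapply(seq_len(n_terms), function(i) {
      size <- sample(seq(term_size_range[1], term_size_range[2]), 1L)
      sort(sample(gene_ids, size))
    })
    names(sets) <- sprintf("term%03d", seq_len(n_terms))
    if (!is.null(planted_term_genes) && n_terms >= 1L) {
      sets[[1L]] <- unique(planted_term_genes)
    }
  })
  gene_set_collection(sets, universe = gene_ids)
}
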