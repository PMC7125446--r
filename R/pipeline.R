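#' Pipeline configuration
#'
#' Defaults reproduce the reference analysis settings: staged FDR cutoffs
#' (0.0005, 0.001, 0.001, 0.001), threshold grid 0.1-0.9, top-20 MD-Gs,
#' enrichment filters (p < 0.01, count >= 3, factor > 1.5) with kappa cut
#' 0.3, and a 200-replicate i.i.d.-normal null experiment.
#'
#' @param cutoffs a [cascade_cutoffs()].
#' @param thresholds threshold grid in (0, 1\].
#' @param k number of MD-Gs to select.
#' @param p_cutoff,min_count,min_factor enrichment filters.
#' @param similarity_cut kappa clustering cut.
#' @param null_model,null_B null-experiment settings (see
#'   [null_separability_probability()]).
#' @param seed integer seed for the null experiment.
#' @param screen run the screening cascade first and restrict the network
#'   stages to flagged genes (`TRUE`, the reference design), or analyze all
#'   genes (`FALSE`; use when connectivity changes, which need not alter
#'   marginal distributions, are the object of interest).
#' @param out_dir optional directory; when given, every stage writes its
#'   table there.
#' @param quiet suppress per-stage log messages.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(cutoffs = cascade_cutoffs(),
                            thresholds = seq(0.1, 0.9, by = 0.1),
                            k = 20,
                            p_cutoff = 0.01, min_count = 3, min_factor = 1.5,
                            similarity_cut = 0.3,
                            null_model = "iid_normal", null_B = 200,
                            seed = 1L, screen = TRUE,
                            out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(cutoffs, "cascade_cutoffs"))
  if (any(thresholds <= 0 | thresholds > 1)) {
    stop_config("thresholds must lie in (0, 1]")
  }
  structure(
    list(cutoffs = cutoffs, thresholds = sort(thresholds), k = k,
         p_cutoff = p_cutoff, min_count = min_count, min_factor = min_factor,
         similarity_cut = similarity_cut,
         null_model = null_model, null_B = null_B,
         seed = as.integer(seed), screen = isTRUE(screen),
         out_dir = out_dir, quiet = isTRUE(quiet)),
    class = "pipeline_config"
  )
}

stage_log <- function(config, stage, ...) {
  if (!config$quiet) {
    message(sprintf("[mdgnet:%s] %s", stage, sprintf(...)))
  }
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)),
          class = c("mdgnet_stage_error", "mdgnet_error"), parent = e)
  })
}

#' Run the full differential network-structure pipeline
#'
#' Executes screen (optional) -> degree sweep -> separability and Monte Carlo
#' null -> MD-G ranking -> enrichment (if gene sets are given) -> function
#' levels and difference statistics. With `config$out_dir` set, each stage
#' writes its table (TSV/JSON) into that directory; runs with the same
#' configuration and seed are fully deterministic.
#'
#' @param control,experimental aligned expression tibbles.
#' @param gene_sets optional [gene_set_collection()] (or path to a GMT file)
#'   for the enrichment stage; when absent that stage is skipped.
#' @param config a [pipeline_config()].
#' @return An `mdg_pipeline` list: `screen` (or `NULL`), `profile`,
#'   `separability`, `null`, `ranking`, `mdg` (top-k ids), `enrichment`,
#'   `clusters`, `function_levels` (the last three `NULL` without gene sets),
#'   `diff_stats`, and `config`.
#' @examples
#' cfg <- sim_config(n_genes = 60, n_samples_c = 25, n_samples_e = 25,
#'                   module_spec = list(list(size = 15, rho_c = 0.9,
#'                                           rho_e = 0.1, n_planted = 3)))
#' ds <- gen_connectivity_dataset(cfg)
#' res <- run_pipeline(ds$control, ds$experimental,
#'                     config = pipeline_config(screen = FALSE, null_B = 50,
#'                                              k = 5, quiet = TRUE))
#' res$mdg
#' @export
run_pipeline <- function(control, experimental, gene_sets = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  pair <- run_stage("input", validate_expr_pair(control, experimental))
  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  if (is.character(gene_sets)) {
    gene_sets <- run_stage("read_gmt", read_gmt(gene_sets))
  }

  scr <- NULL
  if (config$screen) {
    scr <- run_stage("screen",
                     screen_genes(pair$control, pair$experimental,
                                  cutoffs = config$cutoffs))
    keep <- flagged_genes(scr)
    stage_log(config, "screen", "%d/%d genes flagged", length(keep),
              scr$n_genes)
    if (!is.null(out)) {
      write_screen(scr, file.path(out, "screen.tsv"),
                   file.path(out, "flagged_genes.txt"))
    }
    if (length(keep) < 2) {
      abort("fewer than 2 genes flagged; nothing to build a network from",
            class = c("mdgnet_stage_error", "mdgnet_error"))
    }
    pair <- lapply(pair, function(x) x[x$gene_id %in% keep, ])
  }

  profile <- run_stage("degree_sweep",
                       degree_sweep(pair$control, pair$experimental,
                                    thresholds = config$thresholds))
  sep <- separability(profile)
  stage_log(config, "degree_sweep", "%d genes, %d thresholds, separable: %s",
            length(profile$gene_ids), length(config$thresholds),
            sep$separable)

  nul <- run_stage("null_experiment", null_separability_probability(
    n_genes = length(profile$gene_ids),
    n_samples_c = ncol(pair$control) - 1L,
    n_samples_e = ncol(pair$experimental) - 1L,
    thresholds = config$thresholds, B = config$null_B, seed = config$seed,
    model = config$null_model,
    control = pair$control, experimental = pair$experimental))
  stage_log(config, "null_experiment",
            "model %s, B = %d: estimate %.3f (se %.3f)",
            nul$model, nul$B, nul$estimate, nul$se)

  ranking <- run_stage("md_scores", md_scores(profile))
  k <- min(config$k, nrow(ranking))
  mdg <- top_k(ranking, k)
  stage_log(config, "md_scores", "top %d MD-Gs: %s ...", k,
            paste(head(mdg, 5), collapse = ", "))
  if (!is.null(out)) {
    readr::write_tsv(tidy(profile), file.path(out, "degrees.tsv"),
                     progress = FALSE)
    readr::write_tsv(average_degree_table(profile),
                     file.path(out, "average_degree.tsv"), progress = FALSE)
    readr::write_tsv(as_tibble(ranking), file.path(out, "mdg_scores.tsv"),
                     progress = FALSE)
    writeLines(mdg, file.path(out, "mdg_top.txt"))
    jsonlite::write_json(
      glance(nul), file.path(out, "null_separability.json"),
      auto_unbox = TRUE, digits = NA)
  }

  enr <- clusters <- levels <- NULL
  if (!is.null(gene_sets)) {
    enr <- run_stage("enrichment",
                     enrich(mdg, gene_sets, p_cutoff = config$p_cutoff,
                            min_count = config$min_count,
                            min_factor = config$min_factor))
    if (any(enr$retained)) {
      clusters <- run_stage("clustering",
                            cluster_terms(enr, gene_sets,
                                          similarity_cut = config$similarity_cut))
      levels <- run_stage("function_levels",
                          function_levels(cluster_gene_lists(clusters),
                                          pair$control, pair$experimental))
      stage_log(config, "enrichment", "%d terms retained in %d clusters",
                sum(enr$retained), max(clusters$cluster))
    } else {
      stage_log(config, "enrichment", "no terms passed the filters")
    }
    if (!is.null(out)) {
      readr::write_tsv(as_tibble(enr), file.path(out, "enrichment.tsv"),
                       progress = FALSE)
      if (!is.null(clusters)) {
        readr::write_tsv(as_tibble(clusters), file.path(out, "clusters.tsv"),
                         progress = FALSE)
        readr::write_tsv(levels, file.path(out, "function_levels.tsv"),
                         progress = FALSE)
      }
    }
  } else {
    stage_log(config, "enrichment", "skipped (no gene sets)")
  }

  stats <- run_stage("diff_stats",
                     diff_stats(pair$control, pair$experimental, mdg))
  if (!is.null(out)) {
    jsonlite::write_json(as.list(stats), file.path(out, "diff_stats.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  structure(
    list(screen = scr, profile = profile, separability = sep, null = nul,
         ranking = ranking, mdg = mdg, enrichment = enr, clusters = clusters,
         function_levels = levels, diff_stats = stats, config = config),
    class = "mdg_pipeline"
  )
}

#' @export
print.mdg_pipeline <- function(x, ...) {
  cat("<mdg_pipeline>\n")
  if (!is.null(x$screen)) {
    cat(sprintf("  screen: %d/%d genes flagged\n",
                sum(x$screen$records$flagged), x$screen$n_genes))
  }
  cat(sprintf("  network: %d genes, separable: %s\n",
              length(x$profile$gene_ids), x$separability$separable))
  cat(sprintf("  null: estimate %.3f (confidence %.3f, B = %d, %s)\n",
              x$null$estimate, x$null$confidence, x$null$B, x$null$model))
  cat(sprintf("  MD-Gs (top %d): %s\n", length(x$mdg),
              paste(head(x$mdg, 10), collapse = ", ")))
  if (!is.null(x$clusters)) {
    cat(sprintf("  enrichment: %d retained terms, %d clusters\n",
                nrow(x$clusters), max(x$clusters$cluster)))
  }
  invisible(x)
}
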