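# broom-style accessors: tidy() returns the per-unit table of a result,
# glance() a one-row summary.

#' @method tidy gene_screen
#' @export
tidy.gene_screen <- function(x, ...) x$records

#' @method glance gene_screen
#' @export
glance.gene_screen <- function(x, ...) {
  routes <- table(factor(x$records$route,
                         levels = c("ks2_different", "t", "welch",
                                    "mann_whitney")))
  tibble(
    n_genes = x$n_genes,
    n_flagged = sum(x$records$flagged),
    n_ks2_different = unname(routes["ks2_different"]),
    n_t = unname(routes["t"]),
    n_welch = unname(routes["welch"]),
    n_mann_whitney = unname(routes["mann_whitney"]),
    fdr_scope = x$fdr_scope,
    normality = x$normality
  )
}

#' @method tidy degree_profile
#' @export
tidy.degree_profile <- function(x, ...) {
  long <- function(m, cohort) {
    as_tibble(m, rownames = "gene_id") |>
      tidyr::pivot_longer(-"gene_id", names_to = "threshold",
                          values_to = "degree") |>
      dplyr::mutate(threshold = as.numeric(.data$threshold),
                    cohort = cohort)
  }
  dplyr::bind_rows(long(x$deg_c, "control"), long(x$deg_e, "experimental")) |>
    dplyr::relocate("gene_id", "cohort", "threshold", "degree")
}

#' @method glance degree_profile
#' @export
glance.degree_profile <- function(x, ...) {
  sep <- separability(x)
  tibble(n_genes = length(x$gene_ids),
         n_thresholds = length(x$thresholds),
         separable = sep$separable,
         direction = sep$direction)
}

#' @method tidy mdg_ranking
#' @export
tidy.mdg_ranking <- function(x, ...) as_tibble(x)

#' @method glance null_separability
#' @export
glance.null_separability <- function(x, ...) {
  tibble(estimate = x$estimate, se = x$se, confidence = x$confidence,
         B = x$B, seed = x$seed, model = x$model,
         n_genes = x$n_genes, n_samples_c = x$n_samples_c,
         n_samples_e = x$n_samples_e)
}

#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) as_tibble(x)

#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(n_terms = nrow(x), n_retained = sum(x$retained),
         min_p = min(x$p), query_size = x$n[1], universe_size = x$N[1])
}

#' @method tidy enrichment_clusters
#' @export
tidy.enrichment_clusters <- function(x, ...) as_tibble(x)
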