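#' Mean expression of one gene in a cohort
#'
#' @param x expression tibble.
#' @param gene gene identifier present in `x`.
#' @return Arithmetic mean over samples.
#' @export
gene_mean_expression <- function(x, gene) {
  m <- as_expr_matrix(x)
  if (!gene %in% rownames(m)) {
    stop_input(sprintf("gene '%s' not found", gene), "mdgnet_lookup_error")
  }
  mean(m[gene, ])
}

#' Function-level expression totals per cohort
#'
#' The total expression level of a function in a cohort is the sum of its
#' member genes' mean expression in that cohort; the reported difference is
#' the absolute difference of the two totals.
#'
#' @param functions named list of character gene vectors (e.g. from
#'   [cluster_gene_lists()]), or a data frame with `function_id` and
#'   `gene_id` columns.
#' @param control,experimental aligned expression tibbles containing every
#'   member gene.
#' @return A tibble: `function_id`, `n_genes`, `total_control`,
#'   `total_experimental`, `difference`.
#' @export
function_levels <- function(functions, control, experimental) {
  if (is.data.frame(functions)) {
    if (!all(c("function_id", "gene_id") %in% names(functions))) {
      stop_input("functions data frame needs function_id and gene_id columns")
    }
    functions <- split(functions$gene_id, functions$function_id)
  }
  if (!length(functions) || is.null(names(functions))) {
    stop_input("functions must be a non-empty named list")
  }
  pair <- validate_expr_pair(control, experimental)
  mc <- as_expr_matrix(pair$control)
  me <- as_expr_matrix(pair$experimental)
  unknown <- setdiff(unique(unlist(functions)), rownames(mc))
  if (length(unknown)) {
    stop_input(paste0("unknown gene(s) in function mapping: ",
                      paste(head(unknown, 5), collapse = ", ")),
               "mdgnet_lookup_error")
  }
  mean_c <- rowMeans(mc)
  mean_e <- rowMeans(me)
  purrr::imap_dfr(functions, function(genes, id) {
    genes <- unique(genes)
    tc <- sum(mean_c[genes])
    te <- sum(mean_e[genes])
    tibble(function_id = id, n_genes = length(genes),
           total_control = tc, total_experimental = te,
           difference = abs(tc - te))
  })
}

#' Summary statistics of per-gene mean-expression differences
#'
#' For each gene the absolute difference between its cohort mean expressions
#' is computed; the maximum, minimum, mean and variance over the gene list
#' are returned. Population variance (divisor `n`) is the default.
#'
#' @param control,experimental aligned expression tibbles.
#' @param genes character gene list (non-empty, present in both cohorts);
#'   typically the MD-G list.
#' @param variance `"population"` or `"sample"`.
#' @return One-row tibble: `max`, `min`, `mean`, `variance`, `n_genes`.
#' @export
diff_stats <- function(control, experimental, genes,
                       variance = c("population", "sample")) {
  variance <- match.arg(variance)
  if (!length(genes)) stop_input("empty gene list")
  pair <- validate_expr_pair(control, experimental)
  mc <- as_expr_matrix(pair$control)
  me <- as_expr_matrix(pair$experimental)
  genes <- unique(as.character(genes))
  missing <- setdiff(genes, rownames(mc))
  if (length(missing)) {
    stop_input(paste0("gene(s) not found: ", paste(head(missing, 5),
                                                   collapse = ", ")),
               "mdgnet_lookup_error")
  }
  d <- abs(rowMeans(mc[genes, , drop = FALSE]) -
             rowMeans(me[genes, , drop = FALSE]))
  v <- if (variance == "population") mean((d - mean(d))^2) else {
    if (length(d) > 1) var(d) else 0
  }
  tibble(max = max(d), min = min(d), mean = mean(d), variance = v,
         n_genes = length(d))
}
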