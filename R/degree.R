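#' Per-gene degrees across a threshold grid for two cohorts
#'
#' Computes one Spearman correlation matrix per cohort, then re-thresholds it
#' at every grid value, recording each gene's degree and the cohort
#' average-degree curves.
#'
#' @param control,experimental aligned expression tibbles.
#' @param thresholds numeric grid in (0, 1\]; default `seq(0.1, 0.9, 0.1)`.
#' @return A `degree_profile`: list with `thresholds`, `gene_ids`, integer
#'   degree matrices `deg_c` and `deg_e` (genes x thresholds) and `avg`
#'   (tibble `threshold`, `control`, `experimental`). `tidy()` gives the long
#'   per-gene table, `autoplot()` the average-degree curves.
#' @examples
#' pair <- gen_null_pair(20, 10, 10, seed = 1)
#' profile <- degree_sweep(pair$control, pair$experimental)
#' profile$avg
#' @export
degree_sweep <- function(control, experimental,
                         thresholds = seq(0.1, 0.9, by = 0.1)) {
  if (!length(thresholds) || any(thresholds <= 0 | thresholds > 1)) {
    stop_input("thresholds must lie in (0, 1]")
  }
  thresholds <- sort(thresholds)
  pair <- validate_expr_pair(control, experimental)
  degs <- lapply(pair, function(x) {
    a <- round12(abs(correlation_matrix(x)))
    diag(a) <- -Inf
    out <- vapply(thresholds, function(al) rowSums(a >= al), numeric(nrow(a)))
    if (is.null(dim(out))) out <- matrix(out, nrow = nrow(a))
    colnames(out) <- format(thresholds)
    out
  })
  new_degree_profile(pair$control$gene_id, thresholds,
                     degs$control, degs$experimental)
}

new_degree_profile <- function(gene_ids, thresholds, deg_c, deg_e) {
  rownames(deg_c) <- rownames(deg_e) <- gene_ids
  structure(
    list(thresholds = thresholds, gene_ids = gene_ids,
         deg_c = deg_c, deg_e = deg_e,
         avg = tibble(threshold = thresholds,
                      control = unname(colMeans(deg_c)),
                      experimental = unname(colMeans(deg_e)))),
    class = "degree_profile"
  )
}

#' @export
print.degree_profile <- function(x, ...) {
  cat(sprintf("<degree_profile> %d genes over %d thresholds\n",
              length(x$gene_ids), length(x$thresholds)))
  print(x$avg)
  invisible(x)
}

#' Average-degree table in cohort-by-threshold layout
#'
#' One row per cohort, one column per threshold — the layout used for
#' reporting average degrees of the two correlation networks.
#'
#' @param profile a [degree_sweep()] result.
#' @return A tibble with a `cohort` column and one column per threshold.
#' @export
average_degree_table <- function(profile) {
  stopifnot(inherits(profile, "degree_profile"))
  profile$avg |>
    tidyr::pivot_longer(-"threshold", names_to = "cohort", values_to = "avg") |>
    tidyr::pivot_wider(names_from = "threshold", values_from = "avg") |>
    dplyr::arrange(.data$cohort)
}

curves_separable <- function(cc, ee) {
  if (all(cc > ee)) "control" else if (all(ee > cc)) "experimental" else NA_character_
}

#' Strict separability of the cohort average-degree curves
#'
#' The cohorts are separable when one average-degree curve strictly exceeds
#' the other at every threshold on the grid; any tie or crossing means not
#' separable.
#'
#' @param profile a [degree_sweep()] result (or any list carrying an `avg`
#'   tibble with `control` and `experimental` columns on a shared grid).
#' @return A `separability_result`: list with `separable` (logical) and
#'   `direction` (`"control"`, `"experimental"`, or `NA`).
#' @export
separability <- function(profile) {
  if (!is.list(profile) || is.null(profile$avg)) {
    stop_input("profile must carry an 'avg' curve table")
  }
  dir <- curves_separable(profile$avg$control, profile$avg$experimental)
  structure(list(separable = !is.na(dir), direction = dir),
            class = "separability_result")
}

#' @export
print.separability_result <- function(x, ...) {
  if (x$separable) {
    cat(sprintf("<separability> separable, %s dominates at every threshold\n",
                x$direction))
  } else {
    cat("<separability> not separable (tie or crossing on the grid)\n")
  }
  invisible(x)
}

# Average-degree curve of one i.i.d.-normal replicate, from the off-diagonal
# |SCC| values: avg degree at alpha = 2 * #{pairs >= alpha} / n.
null_avg_curve <- function(n_genes, n_samples, thresholds) {
  x <- matrix(rnorm(n_genes * n_samples), n_genes)
  s <- round12(abs(cor(t(x), method = "spearman")))
  v <- s[upper.tri(s)]
  vapply(thresholds, function(al) 2 * sum(v >= al) / n_genes, 0)
}

perm_avg_curve <- function(pooled, idx, thresholds) {
  s <- round12(abs(cor(t(pooled[, idx, drop = FALSE]), method = "spearman")))
  if (anyNA(s)) s[is.na(s)] <- 0
  v <- s[upper.tri(s)]
  vapply(thresholds, function(al) 2 * sum(v >= al) / nrow(pooled), 0)
}

#' Monte Carlo null probability of average-degree separability
#'
#' Estimates how often two cohorts drawn from the *same* distribution
#' nonetheless produce strictly separable average-degree curves over the
#' threshold grid (in either direction). Its complement is the confidence
#' that an observed separability reflects a real structural difference.
#'
#' Two null models are available: `"iid_normal"` draws every entry of both
#' replicate matrices from a standard normal at the given dimensions;
#' `"label_permutation"` pools the supplied cohorts and randomly reassigns
#' sample labels, preserving the real correlation structure.
#'
#' @param n_genes,n_samples_c,n_samples_e dimensions of each replicate pair.
#' @param thresholds threshold grid.
#' @param B number of Monte Carlo replicates (>= 50).
#' @param seed integer seed.
#' @param model `"iid_normal"` or `"label_permutation"`.
#' @param control,experimental expression tibbles, required for
#'   `"label_permutation"` (dimensions are then taken from the data).
#' @return A `null_separability` object: `estimate` (fraction separable),
#'   `se` (binomial standard error), `confidence` (`1 - estimate`), `B`,
#'   `seed`, `model` and `directions` (separable counts per direction).
#' @examples
#' null_separability_probability(30, 10, 10, seq(0.1, 0.5, 0.1),
#'                               B = 50, seed = 1)
#' @export
null_separability_probability <- function(n_genes, n_samples_c, n_samples_e,
                                          thresholds = seq(0.1, 0.9, by = 0.1),
                                          B = 200, seed = 1L,
                                          model = c("iid_normal",
                                                    "label_permutation"),
                                          control = NULL, experimental = NULL) {
  model <- match.arg(model)
  if (B < 50) stop_config("B must be >= 50")
  thresholds <- sort(thresholds)
  if (model == "label_permutation") {
    if (is.null(control) || is.null(experimental)) {
      stop_config("label_permutation needs control and experimental data")
    }
    pair <- validate_expr_pair(control, experimental)
    pooled <- cbind(as_expr_matrix(pair$control), as_expr_matrix(pair$experimental))
    n_genes <- nrow(pooled)
    n_samples_c <- ncol(as_expr_matrix(pair$control))
    n_samples_e <- ncol(pooled) - n_samples_c
  }
  dirs <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(B), function(b) {
      if (model == "iid_normal") {
        cc <- null_avg_curve(n_genes, n_samples_c, thresholds)
        ee <- null_avg_curve(n_genes, n_samples_e, thresholds)
      } else {
        idx <- sample.int(ncol(pooled))
        cc <- perm_avg_curve(pooled, idx[seq_len(n_samples_c)], thresholds)
        ee <- perm_avg_curve(pooled, idx[-seq_len(n_samples_c)], thresholds)
      }
      curves_separable(cc, ee)
    }, NA_character_)
  })
  est <- mean(!is.na(dirs))
  structure(
    list(estimate = est,
         se = sqrt(est * (1 - est) / B),
         confidence = 1 - est,
         B = as.integer(B), seed = as.integer(seed), model = model,
         n_genes = n_genes, n_samples_c = n_samples_c,
         n_samples_e = n_samples_e, thresholds = thresholds,
         directions = c(control = sum(dirs == "control", na.rm = TRUE),
                        experimental = sum(dirs == "experimental", na.rm = TRUE))),
    class = "null_separability"
  )
}

#' @export
print.null_separability <- function(x, ...) {
  cat(sprintf(
    "<null_separability> model %s: estimate %.3f (se %.3f, B = %d), confidence %.3f\n",
    x$model, x$estimate, x$se, x$B, x$confidence))
  invisible(x)
}

#' Rank genes by mean absolute degree difference
#'
#' The score of a gene is the mean over the threshold grid of the absolute
#' difference between its control and experimental degrees — absolute rather
#' than relative change, so the measure does not depend on the baseline
#' degree. Genes are ranked by descending score; ties break by ascending gene
#' identifier.
#'
#' @param profile a [degree_sweep()] result.
#' @return An `mdg_ranking`: tibble with `gene_id`, `score`, `rank`.
#' @export
md_scores <- function(profile) {
  stopifnot(inherits(profile, "degree_profile"))
  score <- rowMeans(abs(profile$deg_c - profile$deg_e))
  out <- tibble(gene_id = profile$gene_ids, score = unname(score)) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$gene_id) |>
    dplyr::mutate(rank = dplyr::row_number())
  class(out) <- c("mdg_ranking", class(out))
  attr(out, "thresholds") <- profile$thresholds
  out
}

#' Top-k maximally structural difference genes
#'
#' @param ranking an [md_scores()] result.
#' @param k number of genes, between 1 and the gene count; default 20.
#' @return Character vector of the first `k` gene ids by descending score
#'   (ties by ascending id).
#' @export
top_k <- function(ranking, k = 20) {
  stopifnot(inherits(ranking, "mdg_ranking"))
  if (length(k) != 1 || k < 1 || k > nrow(ranking)) {
    stop_input("k must lie in [1, gene count]")
  }
  ranking$gene_id[seq_len(k)]
}
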