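#' Spearman rank correlation of two profiles
#'
#' Product-moment correlation of average-ranked values; ties get average
#' ranks. Correlation with a constant profile is undefined and returns the
#' sentinel 0 with a warning (a constant gene should create no network edge).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return The coefficient in \[-1, 1\].
#' @examples
#' spearman_coefficient(c(1, 2, 3), c(3, 1, 2))
#' @export
spearman_coefficient <- function(x, y) {
  if (length(x) != length(y)) stop_input("profiles must have equal length")
  if (length(x) < 3) stop_input("need >= 3 paired values")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant profile: Spearman coefficient undefined, returning 0")
    return(0)
  }
  cor(x, y, method = "spearman")
}

#' Gene-gene Spearman correlation matrix
#'
#' All pairwise Spearman coefficients between gene expression profiles.
#' Constant genes yield undefined correlations; their off-diagonal entries are
#' set to 0 (sentinel, no edge at any positive threshold) with one warning.
#'
#' @param x expression tibble with >= 3 samples.
#' @return Symmetric numeric matrix with unit diagonal and gene ids as
#'   dimnames.
#' @export
correlation_matrix <- function(x) {
  m <- as_expr_matrix(x)
  if (ncol(m) < 3) stop_input("correlation needs >= 3 samples")
  s <- suppressWarnings(cor(t(m), method = "spearman"))
  if (anyNA(s)) {
    warn("constant gene(s): undefined correlations set to 0")
    s[is.na(s)] <- 0
  }
  diag(s) <- 1
  s
}

# Threshold comparisons use values rounded to 12 decimals so that ties at the
# cutoff resolve identically across platforms.
round12 <- function(x) round(x, 12)

#' Threshold a correlation matrix into a network
#'
#' Connects two distinct genes whenever `|SCC| >= alpha` (inclusive); no
#' self-loops.
#'
#' @param s symmetric correlation matrix (as from [correlation_matrix()]).
#' @param alpha threshold in (0, 1\].
#' @return A `threshold_network`: list with `alpha`, `gene_ids`, `edges`
#'   (tibble `gene_a`, `gene_b`, `scc`) and `degree` (tibble `gene_id`,
#'   `degree`).
#' @export
threshold_network <- function(s, alpha) {
  if (!is.matrix(s) || nrow(s) != ncol(s)) stop_input("s must be a square matrix")
  if (length(alpha) != 1 || alpha <= 0 || alpha > 1) {
    stop_input("alpha must lie in (0, 1]")
  }
  ids <- rownames(s)
  if (is.null(ids)) ids <- gene_ids_for(nrow(s))
  a <- round12(abs(s))
  diag(a) <- -Inf
  adj <- a >= alpha
  deg <- rowSums(adj)
  up <- which(upper.tri(s) & adj, arr.ind = TRUE)
  edges <- tibble(
    gene_a = ids[up[, 1]], gene_b = ids[up[, 2]],
    scc = s[up]
  )
  structure(
    list(alpha = alpha, gene_ids = ids, edges = edges,
         degree = tibble(gene_id = ids, degree = unname(deg))),
    class = "threshold_network"
  )
}

#' Average degree of a thresholded network
#'
#' `2m / n`: twice the edge count over the node count; 0 for an empty edge
#' set.
#'
#' @param net a [threshold_network()].
#' @return Mean degree.
#' @export
average_degree <- function(net) {
  stopifnot(inherits(net, "threshold_network"))
  if (!length(net$gene_ids)) stop_input("empty node set")
  mean(net$degree$degree)
}

#' @export
print.threshold_network <- function(x, ...) {
  cat(sprintf("<threshold_network> alpha = %g: %d nodes, %d edges, average degree %.3f\n",
              x$alpha, length(x$gene_ids), nrow(x$edges), average_degree(x)))
  invisible(x)
}

#' Write a network edge list as TSV
#'
#' @param net a [threshold_network()].
#' @param path output path; columns `gene_a`, `gene_b`, `scc`.
#' @return `path`, invisibly.
#' @export
write_edges <- function(net, path) {
  stopifnot(inherits(net, "threshold_network"))
  readr::write_tsv(net$edges, path, progress = FALSE)
  invisible(path)
}
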