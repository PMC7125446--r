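#' Gene-set collection
#'
#' Named terms, each a set of gene ids, plus a background universe. The
#' default universe is the union of all term genes — "all genes in the
#' genome" depends on an annotation release, so it must be supplied
#' explicitly to mean anything else.
#'
#' @param sets named list of character vectors (no empty terms).
#' @param universe optional character background; must contain every term
#'   gene.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (!length(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop_input("sets must be a non-empty named list")
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0L)) stop_input("empty terms are not allowed")
  all_genes <- unique(unlist(sets, use.names = FALSE))
  if (is.null(universe)) {
    universe <- sort(all_genes)
  } else {
    universe <- unique(as.character(universe))
    if (!all(all_genes %in% universe)) {
      stop_input("every term must be a subset of the universe")
    }
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d terms over %d genes (sizes %d-%d)\n",
              length(x$sets), length(x$universe),
              min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for X hypergeometric: `k` successes in a draw of `n` from a
#' universe of `N` containing `K` successes.
#'
#' @param N universe size.
#' @param K term size.
#' @param n query size.
#' @param k observed overlap (0 <= k <= min(K, n)).
#' @return The cumulative upper-tail probability.
#' @examples
#' hypergeom_upper_tail(10, 3, 3, 3) # 1 / choose(10, 3)
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  if (K > N || n > N || k < 0 || k > min(K, n)) {
    stop_input("inconsistent hypergeometric counts")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric gene-set enrichment
#'
#' Tests every term of a collection for over-representation of a query gene
#' list via the upper-tail hypergeometric distribution, adjusts across all
#' tested terms with Benjamini-Hochberg, and retains terms passing the
#' significance, minimum-count and enrichment-factor filters (defaults
#' p < 0.01, overlap >= 3, factor > 1.5; the factor is observed over
#' expected overlap, `k / (K n / N)`).
#'
#' @param query character vector of gene ids; its intersection with the
#'   universe must be non-empty.
#' @param sets a [gene_set_collection()].
#' @param p_cutoff,min_count,min_factor retention filters.
#' @return An `enrichment_result` tibble sorted by ascending p (ties by term
#'   id): `term`, `k`, `K`, `n`, `N`, `p`, `q`, `factor`, `genes`
#'   (overlap, comma-separated), `retained`.
#' @export
enrich <- function(query, sets, p_cutoff = 0.01, min_count = 3,
                   min_factor = 1.5) {
  stopifnot(inherits(sets, "gene_set_collection"))
  query <- unique(as.character(query))
  eff <- sort(intersect(query, sets$universe))
  if (!length(eff)) stop_input("query does not intersect the universe")
  N <- length(sets$universe)
  n <- length(eff)
  res <- purrr::map2_dfr(sets$sets, names(sets$sets), function(genes, term) {
    hit <- intersect(eff, genes)
    k <- length(hit)
    K <- length(genes)
    tibble(term = term, k = k, K = K, n = n, N = N,
           p = hypergeom_upper_tail(N, K, n, k),
           factor = k / (K * n / N),
           genes = paste(sort(hit), collapse = ","))
  })
  res$q <- bh_adjust(res$p)
  res <- res |>
    dplyr::mutate(retained = .data$p < p_cutoff & .data$k >= min_count &
                    .data$factor > min_factor) |>
    dplyr::arrange(.data$p, .data$term) |>
    dplyr::relocate("term", "k", "K", "n", "N", "p", "q", "factor",
                    "genes", "retained")
  class(res) <- c("enrichment_result", class(res))
  attr(res, "query") <- eff
  attr(res, "filters") <- c(p_cutoff = p_cutoff, min_count = min_count,
                            min_factor = min_factor)
  res
}

#' Kappa similarity of two terms over a query
#'
#' Cohen's kappa between the membership indicator vectors of two terms,
#' restricted to the query genes (the DAVID/Metascape convention for grouping
#' enriched terms). When expected agreement is 1 (both indicators constant),
#' kappa is defined as 1 if observed agreement is 1 and 0 otherwise.
#'
#' @param term_a,term_b character gene sets.
#' @param query character query gene list (non-empty).
#' @return Kappa in \[-1, 1\].
#' @export
kappa_similarity <- function(term_a, term_b, query) {
  query <- unique(as.character(query))
  if (!length(query)) stop_input("query must be non-empty")
  a <- query %in% term_a
  b <- query %in% term_b
  po <- mean(a == b)
  pa <- mean(a)
  pb <- mean(b)
  pe <- pa * pb + (1 - pa) * (1 - pb)
  if (pe >= 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

kappa_matrix <- function(sets, query) {
  n <- length(sets)
  k <- diag(1, n)
  dimnames(k) <- list(names(sets), names(sets))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        k[i, j] <- k[j, i] <- kappa_similarity(sets[[i]], sets[[j]], query)
      }
    }
  }
  k
}

#' Cluster retained enriched terms by kappa similarity
#'
#' Hierarchically clusters the retained terms on `1 - kappa` distance
#' (average linkage by default); clusters are the maximal subtrees whose
#' merges all exceed the similarity cut (default > 0.3), singletons allowed.
#' Each cluster's representative is its smallest-p member (ties by term id).
#' Clusters are numbered by their representative's p-value.
#'
#' @param result an [enrich()] result with at least one retained term.
#' @param sets the [gene_set_collection()] used for enrichment.
#' @param similarity_cut kappa threshold; merges at similarity strictly above
#'   it stay in one cluster.
#' @param linkage agglomeration method for [stats::hclust()].
#' @return An `enrichment_clusters` tibble: the retained terms with `cluster`
#'   and `representative` columns; the kappa matrix is attached as an
#'   attribute.
#' @export
cluster_terms <- function(result, sets, similarity_cut = 0.3,
                          linkage = "average") {
  stopifnot(inherits(result, "enrichment_result"),
            inherits(sets, "gene_set_collection"))
  terms <- dplyr::filter(result, .data$retained)
  if (!nrow(terms)) stop_input("no retained terms to cluster")
  query <- attr(result, "query")
  kmat <- kappa_matrix(sets$sets[terms$term], query)
  if (nrow(terms) == 1L) {
    membership <- setNames(1L, terms$term)
  } else {
    tree <- hclust(as.dist(1 - kmat), method = linkage)
    # merges with similarity > cut (height < 1 - cut) share a cluster;
    # the epsilon keeps the cut strict at exactly 1 - similarity_cut
    membership <- cutree(tree, h = (1 - similarity_cut) - 1e-9)
  }
  out <- terms |>
    dplyr::mutate(cluster = unname(membership[.data$term])) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(representative = dplyr::row_number(
      order(.data$p, .data$term)) == 1L) |>
    dplyr::ungroup()
  # renumber clusters by their representative's significance
  lead <- out |>
    dplyr::filter(.data$representative) |>
    dplyr::arrange(.data$p, .data$term)
  remap <- setNames(seq_len(nrow(lead)), lead$cluster)
  out <- out |>
    dplyr::mutate(cluster = unname(remap[as.character(.data$cluster)])) |>
    dplyr::arrange(.data$cluster, .data$p, .data$term)
  class(out) <- c("enrichment_clusters", class(out))
  attr(out, "kappa") <- kmat
  attr(out, "similarity_cut") <- similarity_cut
  attr(out, "linkage") <- linkage
  attr(out, "query") <- query
  out
}

#' Member genes of each cluster representative
#'
#' Convenience accessor: one function-level gene list per cluster, taken as
#' the representative term's overlap with the query — the gene lists used for
#' the function-level expression comparison.
#'
#' @param clusters an [cluster_terms()] result.
#' @return Named list (`P1`, `P2`, ...) of character gene vectors, ordered by
#'   cluster number.
#' @export
cluster_gene_lists <- function(clusters) {
  stopifnot(inherits(clusters, "enrichment_clusters"))
  reps <- dplyr::filter(clusters, .data$representative) |>
    dplyr::arrange(.data$cluster)
  setNames(strsplit(reps$genes, ",", fixed = TRUE),
           paste0("P", reps$cluster))
}
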