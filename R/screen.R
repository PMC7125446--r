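#' Cascade FDR cutoffs
#'
#' One false-discovery-rate cutoff per stage of the screening cascade:
#' two-sample Kolmogorov-Smirnov, one-sample normality KS, variance-ratio F
#' test, and the final location test (pooled t / Welch / Mann-Whitney).
#'
#' @param q_ks2,q_norm,q_f,q_loc FDR cutoffs in (0, 1). Defaults 0.0005,
#'   0.001, 0.001, 0.001.
#' @return A `cascade_cutoffs` object.
#' @export
cascade_cutoffs <- function(q_ks2 = 5e-4, q_norm = 1e-3, q_f = 1e-3,
                            q_loc = 1e-3) {
  vals <- c(q_ks2 = q_ks2, q_norm = q_norm, q_f = q_f, q_loc = q_loc)
  if (any(vals <= 0 | vals >= 1)) stop_config("cutoffs must lie in (0, 1)")
  structure(as.list(vals), class = "cascade_cutoffs")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Tests whether two samples share a distribution via the supremum distance
#' between their empirical distribution functions.
#'
#' @param x,y numeric samples, each with at least 2 values.
#' @param exact `NULL` (decide automatically, as [stats::ks.test()]), `TRUE`
#'   or `FALSE` (asymptotic).
#' @return The two-sided p-value, with the KS statistic attached as
#'   `attr(, "statistic")`.
#' @export
two_sample_ks <- function(x, y, exact = NULL) {
  if (length(x) < 2 || length(y) < 2) stop_input("each sample needs >= 2 values")
  ht <- suppressWarnings(ks.test(x, y, exact = exact))
  structure(unname(ht$p.value), statistic = unname(ht$statistic))
}

#' One-sample normality check
#'
#' Standardizes the sample by its mean and standard deviation and applies the
#' one-sample Kolmogorov-Smirnov test against the standard normal. Because the
#' parameters are estimated, the classical p-value is conservatively biased;
#' `method = "lilliefors"` applies the Lilliefors correction instead.
#' A constant sample is a degenerate input and returns p = 0 (treated as
#' non-normal downstream).
#'
#' @param x numeric sample of at least 3 values.
#' @param method `"ks"` (plain, conservative) or `"lilliefors"`.
#' @return p-value with the test statistic attached as an attribute.
#' @export
normality_ks <- function(x, method = c("ks", "lilliefors")) {
  method <- match.arg(method)
  if (length(x) < 3) stop_input("normality check needs >= 3 values")
  s <- sd(x)
  if (s == 0) return(structure(0, statistic = NA_real_))
  if (method == "lilliefors") {
    ht <- nortest::lillie.test(x)
  } else {
    ht <- suppressWarnings(ks.test((x - mean(x)) / s, "pnorm"))
  }
  structure(unname(ht$p.value), statistic = unname(ht$statistic))
}

#' Two-sided variance-ratio (F) test
#'
#' Two-sided p-value `2 * min(P(F <= f), P(F >= f))`, capped at 1, for the
#' ratio of sample variances — symmetric in the two cohorts.
#'
#' @param x,y numeric samples (>= 2 values, non-zero variance each).
#' @return p-value with the F statistic (`var(x)/var(y)`) as an attribute.
#' @export
variance_f_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop_input("each sample needs >= 2 values")
  vx <- var(x); vy <- var(y)
  if (vx == 0 || vy == 0) {
    stop_input("zero variance: variance-ratio test undefined",
               "mdgnet_degenerate_error")
  }
  f <- vx / vy
  lo <- pf(f, length(x) - 1, length(y) - 1)
  p <- min(1, 2 * min(lo, 1 - lo))
  structure(p, statistic = f)
}

#' Two-sample location test
#'
#' Final stage of the cascade: pooled-variance t test, Welch t test
#' (Satterthwaite degrees of freedom), or Mann-Whitney. Mann-Whitney uses
#' exact enumeration when both samples have at most 8 untied values and the
#' normal approximation with continuity and tie correction otherwise. If all
#' values across both samples are tied the p-value is 1 by convention.
#'
#' @param x,y numeric samples (>= 2 values each).
#' @param route `"t"`, `"welch"` or `"mann_whitney"`.
#' @return Two-sided p-value with the test statistic as an attribute.
#' @export
location_test <- function(x, y, route = c("t", "welch", "mann_whitney")) {
  route <- match.arg(route)
  if (length(x) < 2 || length(y) < 2) stop_input("each sample needs >= 2 values")
  if (length(unique(c(x, y))) == 1L) return(structure(1, statistic = NA_real_))
  if (route %in% c("t", "welch")) {
    if (sd(x) == 0 && sd(y) == 0) {
      # distinct constants: infinitely many SDs apart
      return(structure(0, statistic = Inf))
    }
    ht <- t.test(x, y, var.equal = route == "t")
  } else {
    has_ties <- anyDuplicated(c(x, y)) > 0L
    exact <- !has_ties && max(length(x), length(y)) <= 8
    ht <- suppressWarnings(
      wilcox.test(x, y, exact = exact, correct = TRUE)
    )
  }
  structure(unname(ht$p.value), statistic = unname(ht$statistic))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted q-values, order-preserving with the input.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values of the same length.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop_input("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

pval <- function(x) as.numeric(x)

#' Screen cohort-differential genes with the test cascade
#'
#' Runs the per-gene decision tree: a two-sample KS test first (genes whose
#' distributions differ outright exit flagged); for the rest, a normality
#' check per cohort decides between the parametric branch (variance-ratio F
#' test choosing pooled t vs Welch) and the Mann-Whitney branch. Each stage's
#' p-values form their own Benjamini-Hochberg family — by default across the
#' genes that reach the stage, with the two cohorts' normality checks adjusted
#' as separate families — and are compared against that stage's FDR cutoff.
#' A gene is flagged when it exits at the two-sample KS stage or its final
#' location-test q-value passes the cutoff. Genes with zero variance in a
#' cohort skip the parametric branch and are routed to Mann-Whitney.
#'
#' @param control,experimental expression tibbles with identical `gene_id`
#'   columns (see [expr_table()]); at least 2 samples per cohort.
#' @param cutoffs a [cascade_cutoffs()].
#' @param normality method for [normality_ks()].
#' @param ks2_exact passed to [two_sample_ks()]; the default `FALSE`
#'   (asymptotic) keeps large screens fast and handles ties uniformly.
#' @param fdr_scope `"staged"` adjusts each stage across the genes reaching
#'   it; `"global"` adjusts each stage across all genes (every test is
#'   computed for every gene before walking the tree).
#' @return A `gene_screen` object; `tidy()` returns the per-gene trace
#'   (route, stage p/q values, flag), `glance()` a one-row summary and
#'   [flagged_genes()] the flagged identifiers.
#' @examples
#' ds <- gen_de_dataset(sim_config(n_genes = 50, n_samples_c = 20,
#'                                 n_samples_e = 20,
#'                                 de_blocks = c(mean_shift = 5)))
#' scr <- screen_genes(ds$control, ds$experimental)
#' glance(scr)
#' @export
screen_genes <- function(control, experimental, cutoffs = cascade_cutoffs(),
                         normality = c("ks", "lilliefors"), ks2_exact = FALSE,
                         fdr_scope = c("staged", "global")) {
  normality <- match.arg(normality)
  fdr_scope <- match.arg(fdr_scope)
  pair <- validate_expr_pair(control, experimental)
  mc <- as_expr_matrix(pair$control)
  me <- as_expr_matrix(pair$experimental)
  if (ncol(mc) < 2 || ncol(me) < 2) stop_input("need >= 2 samples per cohort")
  n <- nrow(mc)
  ids <- rownames(mc)

  p_ks2 <- vapply(seq_len(n), function(i) {
    pval(two_sample_ks(mc[i, ], me[i, ], exact = ks2_exact))
  }, 0)
  q_ks2 <- bh_adjust(p_ks2)
  ks2_hit <- q_ks2 <= cutoffs$q_ks2
  rest <- !ks2_hit

  p_norm_c <- p_norm_e <- q_norm_c <- q_norm_e <- rep(NA_real_, n)
  p_f <- q_f <- p_loc <- q_loc <- rep(NA_real_, n)
  route <- ifelse(ks2_hit, "ks2_different", NA_character_)

  norm_fam <- if (fdr_scope == "global") rep(TRUE, n) else rest
  idx <- which(norm_fam)
  p_norm_c[idx] <- vapply(idx, function(i) pval(normality_ks(mc[i, ], normality)), 0)
  p_norm_e[idx] <- vapply(idx, function(i) pval(normality_ks(me[i, ], normality)), 0)
  q_norm_c[idx] <- bh_adjust(p_norm_c[idx])
  q_norm_e[idx] <- bh_adjust(p_norm_e[idx])

  both_normal <- rest & q_norm_c > cutoffs$q_norm & q_norm_e > cutoffs$q_norm
  both_normal[is.na(both_normal)] <- FALSE

  f_fam <- if (fdr_scope == "global") {
    q_norm_c > cutoffs$q_norm & q_norm_e > cutoffs$q_norm
  } else {
    both_normal
  }
  idx <- which(f_fam)
  p_f[idx] <- vapply(idx, function(i) pval(variance_f_test(mc[i, ], me[i, ])), 0)
  q_f[idx] <- bh_adjust(p_f[idx])

  route[rest & both_normal & q_f > cutoffs$q_f] <- "t"
  route[rest & both_normal & q_f <= cutoffs$q_f] <- "welch"
  route[rest & !both_normal] <- "mann_whitney"

  loc_fam <- if (fdr_scope == "global") rep(TRUE, n) else rest
  idx <- which(loc_fam)
  p_loc[idx] <- vapply(idx, function(i) {
    r <- route[i]
    if (is.na(r) || r == "ks2_different") {
      # global scope computes a location p for every gene; use the branch the
      # normality/F stages would pick
      r <- if (both_normal[i]) {
        if (!is.na(q_f[i]) && q_f[i] <= cutoffs$q_f) "welch" else "t"
      } else {
        "mann_whitney"
      }
    }
    pval(location_test(mc[i, ], me[i, ], r))
  }, 0)
  q_loc[idx] <- bh_adjust(p_loc[idx])

  flagged <- ks2_hit | (rest & q_loc <= cutoffs$q_loc)
  flagged[is.na(flagged)] <- FALSE

  blank <- function(v, keep) replace(v, !keep, NA_real_)
  records <- tibble(
    gene_id = ids,
    route = route,
    p_ks2 = p_ks2, q_ks2 = q_ks2,
    p_norm_c = blank(p_norm_c, rest), p_norm_e = blank(p_norm_e, rest),
    q_norm_c = blank(q_norm_c, rest), q_norm_e = blank(q_norm_e, rest),
    p_f = blank(p_f, both_normal), q_f = blank(q_f, both_normal),
    p_loc = blank(p_loc, rest), q_loc = blank(q_loc, rest),
    flagged = flagged
  )
  structure(
    list(records = records, cutoffs = cutoffs, fdr_scope = fdr_scope,
         normality = normality, n_genes = n,
         n_samples = c(control = ncol(mc), experimental = ncol(me))),
    class = "gene_screen"
  )
}

#' Flagged gene identifiers of a screen
#'
#' @param x a `gene_screen`.
#' @return Character vector of flagged gene ids, in input order.
#' @export
flagged_genes <- function(x) {
  stopifnot(inherits(x, "gene_screen"))
  x$records$gene_id[x$records$flagged]
}

#' @export
print.gene_screen <- function(x, ...) {
  cat(sprintf("<gene_screen> %d genes (%d + %d samples), %d flagged\n",
              x$n_genes, x$n_samples[1], x$n_samples[2],
              sum(x$records$flagged)))
  print(dplyr::count(x$records, .data$route, .data$flagged))
  invisible(x)
}

#' Write the screen table and flagged-gene list
#'
#' @param x a `gene_screen`.
#' @param path output TSV path for the full per-gene trace.
#' @param flagged_path optional path for the flagged-gene list (one id per
#'   line).
#' @return `path`, invisibly.
#' @export
write_screen <- function(x, path, flagged_path = NULL) {
  stopifnot(inherits(x, "gene_screen"))
  readr::write_tsv(x$records, path, progress = FALSE)
  if (!is.null(flagged_path)) {
    writeLines(flagged_genes(x), flagged_path)
  }
  invisible(path)
}
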