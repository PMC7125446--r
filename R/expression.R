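#' Build an expression table
#'
#' Expression data move through the package as tibbles with a `gene_id`
#' character column followed by one numeric column per sample
#' (genes as rows, the conventional microarray/RNA layout).
#'
#' @param values numeric matrix, genes in rows and samples in columns.
#' @param gene_ids character vector of row identifiers (unique).
#' @param sample_ids character vector of column identifiers (unique).
#' @return A tibble with `gene_id` plus one column per sample.
#' @examples
#' expr_table(matrix(1:6, 2), c("gA", "gB"), c("s1", "s2", "s3"))
#' @export
expr_table <- function(values, gene_ids = rownames(values),
                       sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%04d", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- sprintf("s%03d", seq_len(ncol(values)))
  if (anyDuplicated(gene_ids)) stop_format("duplicated gene identifiers")
  if (anyDuplicated(sample_ids)) stop_format("duplicated sample identifiers")
  out <- as_tibble(values, .name_repair = "minimal")
  names(out) <- sample_ids
  dplyr::bind_cols(tibble(gene_id = as.character(gene_ids)), out)
}

#' Convert an expression table to a numeric matrix
#'
#' @param x expression tibble (see [expr_table()]).
#' @return Numeric matrix with gene ids as rownames, sample ids as colnames.
#' @export
as_expr_matrix <- function(x) {
  x <- validate_expr(x)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$gene_id
  m
}

validate_expr <- function(x, arg = "expression table") {
  if (!is.data.frame(x) || ncol(x) < 2L) {
    stop_format(paste0(arg, " must be a data frame with a gene_id column ",
                       "plus at least one sample column"))
  }
  if (names(x)[1] != "gene_id") {
    if (!"gene_id" %in% names(x)) {
      stop_format(paste0(arg, " has no gene_id column"))
    }
    x <- dplyr::relocate(x, "gene_id")
  }
  if (anyDuplicated(x$gene_id)) {
    stop_format(paste0("duplicated gene identifiers in ", arg))
  }
  if (!all(vapply(x[-1], is.numeric, logical(1)))) {
    stop_format(paste0("non-numeric sample column in ", arg))
  }
  as_tibble(x)
}

# Both cohorts must carry the same genes in the same order; anything else is
# treated as a user error rather than silently reordered.
validate_expr_pair <- function(control, experimental) {
  control <- validate_expr(control, "control cohort")
  experimental <- validate_expr(experimental, "experimental cohort")
  if (!identical(control$gene_id, experimental$gene_id)) {
    stop_alignment("control and experimental cohorts must share the same gene identifiers in the same order")
  }
  list(control = control, experimental = experimental)
}

#' Read an expression matrix and split it by cohort
#'
#' Reads a genes-as-rows delimited table (first column gene id, header row of
#' sample ids) together with a sample-to-group mapping, and returns one
#' expression table per cohort.
#'
#' @param path path to a tab-delimited expression file.
#' @param groups either a path to a two-column tab-delimited file
#'   (`sample`, `group`) or a data frame with those columns. Exactly two
#'   distinct group labels are required and every sample column must be mapped.
#' @param control_group label in `groups` identifying the control cohort;
#'   defaults to `"C"`.
#' @return Named list with `control` and `experimental` expression tibbles,
#'   genes in file order.
#' @seealso [write_expression()], [expr_table()]
#' @export
read_expression <- function(path, groups, control_group = "C") {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(),
    gene_id = readr::col_character()
  ), progress = FALSE)
  if (names(raw)[1] != "gene_id") names(raw)[1] <- "gene_id"
  raw <- validate_expr(raw, basename(path))

  if (is.character(groups) && length(groups) == 1L) {
    groups <- readr::read_tsv(groups, col_types = "cc", progress = FALSE)
  }
  if (!is.data.frame(groups) || !all(c("sample", "group") %in% names(groups))) {
    stop_format("groups must be (a path to) a table with columns 'sample' and 'group'")
  }
  labels <- unique(groups$group)
  if (length(labels) != 2L) {
    stop_input("exactly two group labels are required", "mdgnet_mapping_error")
  }
  if (!control_group %in% labels) {
    stop_input(sprintf("control_group '%s' not found among group labels", control_group),
               "mdgnet_mapping_error")
  }
  samples <- names(raw)[-1]
  missing <- setdiff(samples, groups$sample)
  if (length(missing)) {
    stop_input(paste0("samples without a group assignment: ",
                      paste(head(missing, 5), collapse = ", ")),
               "mdgnet_mapping_error")
  }
  if (anyDuplicated(groups$sample)) {
    stop_input("duplicated sample in group mapping", "mdgnet_mapping_error")
  }
  grp <- setNames(groups$group, groups$sample)[samples]
  ctrl <- samples[grp == control_group]
  expt <- samples[grp != control_group]
  list(
    control = raw[, c("gene_id", ctrl)],
    experimental = raw[, c("gene_id", expt)]
  )
}

#' Write an expression table as tab-delimited text
#'
#' @param x expression tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  x <- validate_expr(x)
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
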