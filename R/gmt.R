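#' Read a GMT gene-set file
#'
#' GMT dialect: one term per line — name, description, then tab-separated
#' gene ids. Duplicate genes inside a term are deduplicated (set semantics).
#'
#' @param path path to a GMT file.
#' @param universe optional background gene set; defaults to the union of all
#'   term genes.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop_format("empty GMT file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop_format(sprintf("GMT line %d has fewer than 3 fields", bad[1]))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop_format("duplicated term names in GMT")
  col <- gene_set_collection(sets, universe = universe)
  attr(col, "descriptions") <- setNames(vapply(fields, `[[`, "", 2L),
                                        names(sets))
  col
}

#' Write a gene-set collection as GMT
#'
#' @param sets a [gene_set_collection()].
#' @param path output path.
#' @param descriptions optional named character descriptions per term;
#'   defaults to `"na"`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(inherits(sets, "gene_set_collection"))
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "descriptions")
  }
  lines <- vapply(names(sets$sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions)) {
      descriptions[[nm]]
    } else {
      "na"
    }
    paste(c(nm, desc, sets$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
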