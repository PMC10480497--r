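#' Expression matrix with a declared unit
#'
#' The package passes gene-by-sample expression around as a plain numeric
#' matrix (genes in rows, samples in columns, both dimnames set) carrying a
#' `"unit"` attribute. Recognised units are `"counts"`, `"TPM"`, `"pTPM"`,
#' `"nTPM"` and `"centered-log"`. Values must be non-negative except in
#' centered-log space.
#'
#' @param values numeric matrix, genes in rows and samples in columns, with
#'   unique row and column names.
#' @param unit one of `"counts"`, `"TPM"`, `"pTPM"`, `"nTPM"`,
#'   `"centered-log"`.
#' @return `values` with the `"unit"` attribute set.
#' @examples
#' m <- expr_matrix(matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2"))),
#'                  unit = "TPM")
#' expr_unit(m)
#' @export
expr_matrix <- function(values,
                        unit = c("counts", "TPM", "pTPM", "nTPM", "centered-log")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs in expression matrix")
  if (unit != "centered-log" && any(values < 0, na.rm = TRUE))
    stop("negative values are only allowed in centered-log unit")
  attr(values, "unit") <- unit
  values
}

#' @rdname expr_matrix
#' @param m an expression matrix.
#' @export
expr_unit <- function(m) {
  u <- attr(m, "unit")
  if (is.null(u)) "unknown" else u
}

.check_unit <- function(m, expected, what) {
  u <- expr_unit(m)
  if (u != "unknown" && !u %in% expected)
    stop(sprintf("%s expects unit %s, got %s", what,
                 paste(expected, collapse = "/"), u))
  invisible(TRUE)
}

#' Read and write gene-by-sample expression matrices as TSV
#'
#' Tab-separated text with the first column holding gene IDs and the header
#' row holding sample IDs, the layout used for all matrices in this package.
#'
#' @param path file path.
#' @param unit declared unit of the stored values (see [expr_matrix()]).
#' @return `read_expression_tsv()` returns an expression matrix;
#'   `write_expression_tsv()` returns `path` invisibly.
#' @export
read_expression_tsv <- function(path, unit = "nTPM") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  expr_matrix(m, unit = unit)
}

#' @rdname read_expression_tsv
#' @param m expression matrix to write.
#' @param id_column header name for the gene-ID column.
#' @export
write_expression_tsv <- function(m, path, id_column = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write gene sets in GMT format
#'
#' One set per line: set name, description, then tab-separated gene IDs.
#'
#' @param path file path.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1), USE.NAMES = FALSE)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors of gene IDs.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, genes)
    paste(c(nm, desc, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}
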