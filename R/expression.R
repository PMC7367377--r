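#' Expression matrix with tumor/normal labels
#'
#' Lightweight container for a genes x samples expression matrix together with
#' a per-sample class label (`"tumor"` or `"normal"`). Values are arbitrary
#' nonnegative expression units; no transformation is applied by the package.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). All values must be finite.
#' @param sample_class character vector of `"tumor"`/`"normal"`, one per
#'   column, named or in column order.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `sample_class`.
#' @export
expression_matrix <- function(values, sample_class) {
  if (!is.matrix(values) || !is.numeric(values)) {
    ssnet_error("`values` must be a numeric matrix", "ssnet_format_error")
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    ssnet_error("`values` must have row and column names", "ssnet_format_error")
  }
  if (anyDuplicated(gene_ids)) {
    ssnet_error("duplicate gene ids", "ssnet_format_error")
  }
  if (anyDuplicated(sample_ids)) {
    ssnet_error("duplicate sample ids", "ssnet_format_error")
  }
  if (!all(is.finite(values))) {
    ssnet_error("expression values must be finite", "ssnet_format_error")
  }
  if (!is.null(names(sample_class))) {
    missing <- setdiff(sample_ids, names(sample_class))
    if (length(missing)) {
      ssnet_error(paste0("samples missing from class map: ",
                         paste(missing, collapse = ", ")),
                  "ssnet_labeling_error")
    }
    sample_class <- sample_class[sample_ids]
  }
  if (length(sample_class) != ncol(values)) {
    ssnet_error("one class label per sample required", "ssnet_labeling_error")
  }
  sample_class <- as.character(sample_class)
  if (!all(sample_class %in% c("tumor", "normal"))) {
    ssnet_error("sample classes must be 'tumor' or 'normal'", "ssnet_labeling_error")
  }
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         sample_class = stats::setNames(sample_class, sample_ids)),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d tumor, %d normal)\n",
              length(x$gene_ids), length(x$sample_ids),
              sum(x$sample_class == "tumor"), sum(x$sample_class == "normal")))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by genes and/or samples
#'
#' @param expr an [expression_matrix()].
#' @param genes,samples character vectors of ids to keep (default: all), in
#'   the order given.
#' @return An `expression_matrix` restricted to the requested rows/columns.
#' @export
subset_expression <- function(expr, genes = NULL, samples = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  genes <- if (is.null(genes)) expr$gene_ids else genes
  samples <- if (is.null(samples)) expr$sample_ids else samples
  if (!all(genes %in% expr$gene_ids)) {
    ssnet_error("unknown gene ids in subset", "ssnet_alignment_error")
  }
  if (!all(samples %in% expr$sample_ids)) {
    ssnet_error("unknown sample ids in subset", "ssnet_alignment_error")
  }
  expression_matrix(expr$values[genes, samples, drop = FALSE],
                    expr$sample_class[samples])
}

#' Read an expression table from TSV
#'
#' Expects a tab-separated file with gene ids in the first column and a header
#' row of sample ids. Class labels come from `class_map`; every sample in the
#' file must be present in it.
#'
#' @param path file path.
#' @param class_map named character vector mapping sample id to
#'   `"tumor"`/`"normal"`.
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, class_map) {
  df <- read_tsv_plain(path)
  if (ncol(df) < 2) ssnet_error("expression table needs >= 2 columns", "ssnet_format_error")
  gene_ids <- as.character(df[[1]])
  if (anyDuplicated(gene_ids)) {
    ssnet_error("duplicate gene id in expression table", "ssnet_format_error")
  }
  raw <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(
    matrix(as.numeric(raw), nrow(raw), ncol(raw), dimnames = dimnames(raw)))
  if (anyNA(vals)) {
    bad <- unique(gene_ids[rowSums(is.na(vals)) > 0])
    ssnet_error(paste0("unparseable values for gene(s): ",
                       paste(utils::head(bad, 5), collapse = ", ")),
                "ssnet_format_error")
  }
  rownames(vals) <- gene_ids
  expression_matrix(vals, class_map)
}

#' Write an expression table to TSV
#'
#' @param expr an [expression_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  full <- apply(expr$values, 2, function(col) sprintf("%.17g", col))
  if (is.null(dim(full))) full <- matrix(full, nrow = 1)
  dimnames(full) <- dimnames(expr$values)
  df <- data.frame(gene = expr$gene_ids, full, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
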