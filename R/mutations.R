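#' Read a minimal mutation table (MAF subset)
#'
#' Reads the four MAF columns the pipeline uses: `Hugo_Symbol`,
#' `Tumor_Sample_Barcode`, `Variant_Classification`, `Variant_Type`. Any
#' further columns are ignored.
#'
#' @param path tab-separated file with a header.
#' @return A data.frame of class `mutation_table` with columns `sample_id`,
#'   `gene_id`, `variant_classification`, `variant_type`.
#' @export
read_mutation_table <- function(path) {
  df <- read_tsv_plain(path)
  required <- c("Hugo_Symbol", "Tumor_Sample_Barcode",
                "Variant_Classification", "Variant_Type")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    ssnet_error(paste0("mutation table missing column(s): ",
                       paste(missing_cols, collapse = ", ")),
                "ssnet_format_error")
  }
  out <- data.frame(
    sample_id = as.character(df$Tumor_Sample_Barcode),
    gene_id = as.character(df$Hugo_Symbol),
    variant_classification = as.character(df$Variant_Classification),
    variant_type = as.character(df$Variant_Type),
    stringsAsFactors = FALSE
  )
  class(out) <- c("mutation_table", "data.frame")
  out
}

#' Summarize a mutation table
#'
#' Plain tabular summary of a mutation table: counts per variant
#' classification, counts per variant type, and genes ranked by the number of
#' distinct mutated samples (ties broken alphabetically).
#'
#' @param mutations a `mutation_table` from [read_mutation_table()] or
#'   [generate_mutations()].
#' @param top_n how many top genes to keep in the ranking (default all).
#' @return A list with data.frames `by_classification`, `by_type`,
#'   `top_genes` (columns `gene_id`, `n_samples`, `n_mutations`).
#' @export
summarize_mutations <- function(mutations, top_n = Inf) {
  stopifnot(inherits(mutations, "data.frame"))
  if (!nrow(mutations)) {
    empty_cnt <- data.frame(level = character(0), count = integer(0))
    return(list(by_classification = empty_cnt, by_type = empty_cnt,
                top_genes = data.frame(gene_id = character(0),
                                       n_samples = integer(0),
                                       n_mutations = integer(0))))
  }
  tab <- function(x) {
    t <- table(x)
    data.frame(level = names(t), count = as.integer(t),
               stringsAsFactors = FALSE)
  }
  per_gene_samples <- tapply(mutations$sample_id, mutations$gene_id,
                             function(s) length(unique(s)))
  per_gene_total <- table(mutations$gene_id)
  genes <- names(per_gene_samples)
  ord <- order(-as.integer(per_gene_samples), genes)
  top <- data.frame(gene_id = genes[ord],
                    n_samples = as.integer(per_gene_samples)[ord],
                    n_mutations = as.integer(per_gene_total[genes])[ord],
                    stringsAsFactors = FALSE)
  if (is.finite(top_n)) top <- utils::head(top, top_n)
  rownames(top) <- NULL
  list(by_classification = tab(mutations$variant_classification),
       by_type = tab(mutations$variant_type),
       top_genes = top)
}
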