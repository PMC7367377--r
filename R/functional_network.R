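# Functional-network aggregation: subtract edges seen in any normal-sample
# SSN from each tumor SSN, then keep edges present in more than a frequency
# threshold (default 90%) of tumor-specific SSNs.

ssn_edge_keys <- function(ssn) {
  if (!nrow(ssn$edges)) return(character(0))
  edge_key(ssn$edges$gene_a, ssn$edges$gene_b)
}

#' Remove normal-SSN edges from a tumor SSN
#'
#' Deletes from the tumor SSN every edge that appears in the union of the
#' normal-sample SSN edge sets, leaving the tumor-specific SSN.
#'
#' @param tumor_ssn an `ssn` (from [build_ssn()]).
#' @param normal_ssns nonempty list of normal-sample `ssn` objects.
#' @return The tumor `ssn` with normal edges removed (possibly empty).
#' @export
tumor_specific_ssn <- function(tumor_ssn, normal_ssns) {
  stopifnot(inherits(tumor_ssn, "ssn"))
  if (!length(normal_ssns)) {
    ssnet_error("normal_ssns must be nonempty", "ssnet_config_error")
  }
  normal_union <- unique(unlist(lapply(normal_ssns, ssn_edge_keys)))
  keep <- !(ssn_edge_keys(tumor_ssn) %in% normal_union)
  out <- tumor_ssn
  out$edges <- tumor_ssn$edges[keep, , drop = FALSE]
  rownames(out$edges) <- NULL
  out
}

#' Aggregate tumor-specific SSNs into the functional network
#'
#' An edge is kept iff the fraction of tumor SSNs containing it is strictly
#' greater than `freq_threshold`. The denominator is the number of tumor
#' samples supplied, not the number of nonempty SSNs.
#'
#' @param specific_ssns list of tumor-specific `ssn` objects (after
#'   [tumor_specific_ssn()]).
#' @param freq_threshold frequency threshold in (0, 1); default 0.9 ("more
#'   than 90% of tumor SSNs").
#' @return A `functional_network`: list with `edges` (data.frame `gene_a`,
#'   `gene_b`, `frequency`), `genes`, `degree` (named integer vector),
#'   `n_tumors`, `freq_threshold`.
#' @export
aggregate_functional_network <- function(specific_ssns, freq_threshold = 0.9) {
  if (!length(specific_ssns)) {
    ssnet_error("need at least one tumor-specific SSN", "ssnet_config_error")
  }
  if (freq_threshold <= 0 || freq_threshold >= 1) {
    ssnet_error("freq_threshold must be in (0, 1)", "ssnet_config_error")
  }
  m <- length(specific_ssns)
  keys <- unlist(lapply(specific_ssns, ssn_edge_keys))
  counts <- if (length(keys)) table(keys) else table(character(0))
  freq <- as.numeric(counts) / m
  keep <- freq > freq_threshold
  kept_keys <- names(counts)[keep]
  ends <- split_edge_key(kept_keys)
  ord <- order(ends$gene_a, ends$gene_b)
  edges <- data.frame(gene_a = ends$gene_a[ord], gene_b = ends$gene_b[ord],
                      frequency = freq[keep][ord], stringsAsFactors = FALSE)
  genes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  deg <- table(factor(c(edges$gene_a, edges$gene_b), levels = genes))
  structure(list(edges = edges, genes = genes,
                 degree = stats::setNames(as.integer(deg), genes),
                 n_tumors = m, freq_threshold = freq_threshold),
            class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  cat(sprintf("functional_network: %d genes, %d edges (frequency > %g over %d tumors)\n",
              length(x$genes), nrow(x$edges), x$freq_threshold, x$n_tumors))
  invisible(x)
}

#' Core functional genes by degree
#'
#' Genes whose degree in the functional network strictly exceeds
#' `degree_threshold` ("degree over 3" means degree >= 4).
#'
#' @param functional_net a `functional_network`.
#' @param degree_threshold nonnegative integer threshold.
#' @return Character vector of core gene ids.
#' @export
core_genes <- function(functional_net, degree_threshold = 3) {
  stopifnot(inherits(functional_net, "functional_network"))
  if (degree_threshold < 0) ssnet_error("degree_threshold must be >= 0", "ssnet_config_error")
  names(functional_net$degree)[functional_net$degree > degree_threshold]
}

#' Node-degree histogram of the functional network
#'
#' @param functional_net a nonempty `functional_network`.
#' @return A data.frame with columns `degree` and `count`; counts sum to the
#'   number of functional genes.
#' @export
degree_distribution <- function(functional_net) {
  stopifnot(inherits(functional_net, "functional_network"))
  if (!length(functional_net$genes)) {
    ssnet_error("empty functional network", "ssnet_empty_result_error")
  }
  t <- table(functional_net$degree)
  data.frame(degree = as.integer(names(t)), count = as.integer(t))
}

#' Write a functional network (edges and genes) as TSV
#'
#' @param functional_net a `functional_network`.
#' @param prefix output path prefix; writes `<prefix>_edges.tsv`
#'   (`geneA`, `geneB`, `frequency`) and `<prefix>_genes.tsv`
#'   (`gene`, `degree`, `is_core`).
#' @param degree_core threshold for the `is_core` flag.
#' @return The prefix, invisibly.
#' @export
write_functional_network <- function(functional_net, prefix, degree_core = 3) {
  params <- list(freq = functional_net$freq_threshold,
                 tumors = functional_net$n_tumors, degree_core = degree_core)
  write_tsv_with_header(
    data.frame(geneA = functional_net$edges$gene_a,
               geneB = functional_net$edges$gene_b,
               frequency = functional_net$edges$frequency),
    paste0(prefix, "_edges.tsv"), params)
  core <- core_genes(functional_net, degree_core)
  write_tsv_with_header(
    data.frame(gene = functional_net$genes,
               degree = as.integer(functional_net$degree),
               is_core = functional_net$genes %in% core),
    paste0(prefix, "_genes.tsv"), params)
  invisible(prefix)
}
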