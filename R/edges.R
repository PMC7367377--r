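#' Scored edge list
#'
#' A set of unordered gene pairs with nonnegative integer confidence scores,
#' in the style of a STRING database export (columns `protein1`, `protein2`,
#' `score`). Self-loops are dropped and duplicate/reversed pairs collapsed to
#' the maximum score.
#'
#' @param gene_a,gene_b character vectors of endpoint gene ids.
#' @param score integer vector of scores, `>= 0`.
#' @return A `scored_edge_list`: data.frame with columns `gene_a`, `gene_b`
#'   (lexicographically ordered within each row), `score`, one row per
#'   unordered pair.
#' @export
scored_edge_list <- function(gene_a, gene_b, score) {
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  if (!is.numeric(score) || any(!is.finite(score)) || any(score != round(score))) {
    ssnet_error("edge scores must be integers", "ssnet_format_error")
  }
  if (any(score < 0)) ssnet_error("edge scores must be >= 0", "ssnet_format_error")
  keep <- gene_a != gene_b
  gene_a <- gene_a[keep]; gene_b <- gene_b[keep]; score <- score[keep]
  key <- edge_key(gene_a, gene_b)
  best <- tapply(score, key, max)
  ends <- split_edge_key(names(best))
  out <- data.frame(gene_a = ends$gene_a, gene_b = ends$gene_b,
                    score = as.integer(unname(best)), stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("scored_edge_list", "data.frame")
  out
}

#' Read a scored edge list, keeping high-confidence edges
#'
#' Reads whitespace- or tab-separated columns (`geneA`, `geneB`, `score`) and
#' keeps edges with `score > min_score` (strict inequality, matching the usual
#' "score above threshold" confidence filter). Reversed and duplicated pairs
#' collapse to one edge with the maximum score; self-loops are dropped.
#'
#' @param path file path. A header line is detected and skipped when the third
#'   field is non-numeric.
#' @param min_score integer; edges must score strictly above this to be kept.
#' @return A [scored_edge_list()].
#' @export
read_scored_edges <- function(path, min_score = 300) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) ssnet_error("empty edge file", "ssnet_format_error")
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3)) ssnet_error("edge lines need 3 columns", "ssnet_format_error")
  first_score <- fields[[1]][3]
  if (is.na(suppressWarnings(as.numeric(first_score)))) fields <- fields[-1]
  a <- vapply(fields, `[`, character(1), 1L)
  b <- vapply(fields, `[`, character(1), 2L)
  s_chr <- vapply(fields, `[`, character(1), 3L)
  s <- suppressWarnings(as.numeric(s_chr))
  if (anyNA(s) || any(s != round(s))) {
    ssnet_error("non-integer edge score", "ssnet_format_error")
  }
  keep <- s > min_score
  if (!any(keep)) {
    return(scored_edge_list(character(0), character(0), integer(0)))
  }
  scored_edge_list(a[keep], b[keep], s[keep])
}

#' Write a scored edge list as TSV
#'
#' @param edges a [scored_edge_list()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scored_edges <- function(edges, path) {
  utils::write.table(
    data.frame(protein1 = edges$gene_a, protein2 = edges$gene_b, score = edges$score),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
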