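#' ssnet: sample-specific network functional biomarkers
#'
#' Per-sample differential-correlation networks from a tumor/normal
#' expression cohort, frequency-aggregated into a functional network whose
#' genes and edges are screened as diagnostic, subtyping and prognostic
#' biomarkers. See `vignette("ssn-functional-biomarkers")` for the methods.
#'
#' @keywords internal
"_PACKAGE"

# Canonical undirected edge key: endpoints sorted lexicographically, joined by "|".
# Gene ids are opaque case-sensitive strings throughout the package.
edge_key <- function(a, b) {
  swap <- a > b
  key <- character(length(a))
  key[!swap] <- paste(a[!swap], b[!swap], sep = "|")
  key[swap] <- paste(b[swap], a[swap], sep = "|")
  key
}

split_edge_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)
  data.frame(
    gene_a = vapply(parts, `[`, character(1), 1L),
    gene_b = vapply(parts, `[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
}

ssnet_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ssnet_error")))
}

# Header comment written at the top of every output TSV.
output_header <- function(params = NULL) {
  info <- sprintf("# ssnet %s", as.character(utils::packageVersion("ssnet")))
  if (length(params)) {
    info <- paste0(info, " | ", paste(names(params), unlist(params), sep = "=", collapse = " "))
  }
  info
}

write_tsv_with_header <- function(df, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
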