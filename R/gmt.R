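#' Gene-set collection
#'
#' Named gene sets plus the size of the reference gene universe used for
#' over-representation testing. The universe size is always supplied
#' explicitly by the caller; it is never inferred from the sets.
#'
#' @param sets named list of character vectors (gene ids); names unique,
#'   sets nonempty.
#' @param universe_size positive integer, total genes in the reference
#'   universe (`N` of the hypergeometric test), or `NA` if not yet set.
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, universe_size = NA_integer_) {
  if (!length(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    ssnet_error("sets must be a nonempty named list", "ssnet_format_error")
  }
  if (anyDuplicated(names(sets))) {
    ssnet_error("duplicate set names", "ssnet_format_error")
  }
  if (any(lengths(sets) == 0)) {
    ssnet_error("empty gene set", "ssnet_format_error")
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  structure(list(sets = sets, universe_size = as.integer(universe_size)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (universe N = %s)\n",
              length(x$sets),
              if (is.na(x$universe_size)) "unset" else x$universe_size))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then gene ids. Lines with fewer than three fields (i.e. no
#' genes) are rejected.
#'
#' @param path GMT file path.
#' @param universe_size optional universe size to attach (see
#'   [gene_set_collection()]).
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe_size = NA_integer_) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3)) {
    ssnet_error("GMT line with fewer than 3 fields", "ssnet_format_error")
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  gene_set_collection(sets, universe_size)
}

#' Write gene sets in GMT format
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  nm <- names(collection$sets)
  if (is.null(descriptions)) descriptions <- rep("na", length(nm))
  lines <- vapply(seq_along(nm), function(i) {
    paste(c(nm[i], descriptions[i], collection$sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
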