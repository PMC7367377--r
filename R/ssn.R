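# Sample-specific network construction.
#
# The reference network is the score-filtered background restricted to
# expressed genes, with a Pearson correlation per edge over the normal
# (reference) samples. Adding one query sample to the reference cohort
# perturbs each edge's correlation; the differential correlation
# delta_pcc = pcc_perturbed - pcc_ref is tested with
#   z = delta_pcc / ((1 - pcc_ref^2) / (n_ref - 1)),
# a standard-normal two-sided null, and significant edges form that sample's
# SSN.

#' Filter genes by expressed-sample fraction
#'
#' Keeps gene `g` iff the fraction of samples with value strictly greater
#' than 0 is at least `min_fraction` (i.e. a gene is removed only when its
#' zero fraction strictly exceeds `1 - min_fraction`). Gene order is
#' preserved.
#'
#' @param expr an [expression_matrix()].
#' @param min_fraction required expressed fraction, in (0, 1].
#' @return The filtered [expression_matrix()].
#' @export
filter_expressed_genes <- function(expr, min_fraction = 0.5) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (min_fraction <= 0 || min_fraction > 1) {
    ssnet_error("min_fraction must be in (0, 1]", "ssnet_config_error")
  }
  frac <- rowMeans(expr$values > 0)
  keep <- frac >= min_fraction
  if (!any(keep)) ssnet_error("all genes removed by expression filter", "ssnet_empty_result_error")
  expression_matrix(expr$values[keep, , drop = FALSE], expr$sample_class)
}

#' Restrict a scored edge list to expressed genes
#'
#' Builds the reference-network skeleton: background edges whose both
#' endpoints are present in the expression matrix.
#'
#' @param edges a [scored_edge_list()] (already score-filtered).
#' @param expr an [expression_matrix()] of the genes to keep.
#' @return A `reference_network` skeleton (edge table without correlations);
#'   pass to [compute_reference_pcc()].
#' @export
build_background <- function(edges, expr) {
  stopifnot(inherits(edges, "scored_edge_list"), inherits(expr, "expression_matrix"))
  keep <- edges$gene_a %in% expr$gene_ids & edges$gene_b %in% expr$gene_ids
  if (!any(keep)) ssnet_error("no background edge has both endpoints expressed",
                              "ssnet_empty_result_error")
  ed <- edges[keep, c("gene_a", "gene_b"), drop = FALSE]
  rownames(ed) <- NULL
  structure(list(edges = as.data.frame(ed), genes = sort(unique(c(ed$gene_a, ed$gene_b))),
                 pcc_ref = NULL, n_ref = NA_integer_),
            class = "reference_network")
}

#' @export
print.reference_network <- function(x, ...) {
  cat(sprintf("reference_network: %d genes, %d edges%s\n",
              length(x$genes), nrow(x$edges),
              if (is.na(x$n_ref)) " (skeleton, no correlations yet)"
              else sprintf(", pcc over %d reference samples", x$n_ref)))
  invisible(x)
}

#' Annotate the reference network with per-edge Pearson correlations
#'
#' Computes each edge's Pearson correlation over the reference (normal)
#' samples and caches the per-gene and per-edge sufficient statistics used by
#' the incremental perturbed-correlation update in [build_ssn()]. Edges with a
#' constant endpoint get an undefined (`NA`) correlation and are excluded from
#' downstream testing, as are edges with `|pcc_ref| = 1` (the test statistic
#' is undefined there); the count of excluded edges is stored in
#' `$n_degenerate`.
#'
#' @param skeleton a `reference_network` from [build_background()].
#' @param expr_ref an [expression_matrix()] restricted to the reference
#'   (normal) samples; needs >= 3 samples.
#' @return The `reference_network` with `pcc_ref`, `n_ref`, `testable` and
#'   cached sufficient statistics filled in.
#' @export
compute_reference_pcc <- function(skeleton, expr_ref) {
  stopifnot(inherits(skeleton, "reference_network"),
            inherits(expr_ref, "expression_matrix"))
  if (any(expr_ref$sample_class != "normal")) {
    ssnet_error("reference expression must contain only normal samples",
                "ssnet_alignment_error")
  }
  n <- length(expr_ref$sample_ids)
  if (n < 3) ssnet_error("need >= 3 reference samples", "ssnet_insufficient_reference_error")
  missing <- setdiff(skeleton$genes, expr_ref$gene_ids)
  if (length(missing)) {
    ssnet_error("reference expression missing network genes", "ssnet_alignment_error")
  }
  x <- expr_ref$values[skeleton$genes, , drop = FALSE]
  ia <- match(skeleton$edges$gene_a, skeleton$genes)
  ib <- match(skeleton$edges$gene_b, skeleton$genes)
  s <- rowSums(x)
  q <- rowSums(x^2)
  cross <- rowSums(x[ia, , drop = FALSE] * x[ib, , drop = FALSE])
  var_n <- n * q - s^2
  denom <- sqrt(pmax(var_n[ia], 0) * pmax(var_n[ib], 0))
  pcc <- ifelse(denom > 0, (n * cross - s[ia] * s[ib]) / denom, NA_real_)
  pcc <- pmin(1, pmax(-1, pcc))
  testable <- !is.na(pcc) & abs(pcc) < 1
  out <- skeleton
  out$pcc_ref <- pcc
  out$n_ref <- n
  out$testable <- testable
  out$n_degenerate <- sum(!testable)
  out$stats <- list(sum = s, sumsq = q, cross = cross, ia = ia, ib = ib)
  out$ref_values <- x
  out
}

# Two-sided tail of the product of two independent standard normals,
# P(|UV| > z). This is the asymptotic null of the scaled differential
# correlation z = delta_pcc * (n - 1) / (1 - pcc_ref^2) when one fresh sample
# is added to n reference samples: writing the added point in the principal
# axes of the reference correlation gives z -> (U^2 - V^2)/2 = product of two
# independent standard normals. Evaluated through a cached monotone spline of
# the log-tail (Bessel-K integral), with the asymptotic expansion beyond the
# grid.
.ssnet_cache <- new.env(parent = emptyenv())

normal_product_tail_interpolator <- function() {
  if (!is.null(.ssnet_cache$np_tail)) return(.ssnet_cache$np_tail)
  tail_one <- function(z) {
    if (z < 1) {
      4 * stats::integrate(function(u) stats::dnorm(u) * stats::pnorm(z / u, lower.tail = FALSE),
                           0, Inf, rel.tol = 1e-12)$value
    } else {
      # (2/pi) * exp(-z) * int_0^inf K0e(z+s) exp(-s) ds, K0e = scaled Bessel K0
      i <- stats::integrate(function(s) besselK(z + s, 0, expon.scaled = TRUE) * exp(-s),
                            0, Inf, rel.tol = 1e-12)$value
      exp(-z) * 2 / pi * i
    }
  }
  zs <- seq(0, 45, by = 0.02)
  logp <- vapply(zs, function(z) log(tail_one(z)), numeric(1))
  fun <- stats::splinefun(zs, logp, method = "hyman")
  .ssnet_cache$np_tail <- function(z) {
    z <- abs(z)
    out <- numeric(length(z))
    inside <- z <= 45
    out[inside] <- exp(fun(z[inside]))
    if (any(!inside)) {
      zz <- z[!inside]
      out[!inside] <- sqrt(2 / (pi * zz)) * exp(-zz) * (1 - 1 / (8 * zz))
    }
    out
  }
  .ssnet_cache$np_tail
}

#' Differential-correlation significance statistic
#'
#' For an edge with reference correlation `pcc_ref` over `n_ref` reference
#' samples and differential correlation `delta_pcc` after adding one sample:
#' `z = delta_pcc / ((1 - pcc_ref^2) / (n_ref - 1))`. Under
#' `null = "normal"` (the default, the canonical form of the single-sample
#' network statistic) the two-sided p-value uses a standard-normal tail.
#' `null = "product"` instead uses the statistic's exact asymptotic null -
#' the product of two independent standard normals, `z -> (U^2 - V^2)/2` -
#' whose tails are much heavier than Gaussian; this calibrates extreme
#' p-values and is the recommended choice whenever small p-values matter
#' (e.g. per-sample multiple-testing correction before cohort-level
#' aggregation). Vectorized over edges.
#'
#' @param pcc_ref reference correlation(s), `|pcc_ref| < 1`.
#' @param delta_pcc differential correlation(s).
#' @param n_ref number of reference samples, >= 3.
#' @param null `"normal"` or `"product"` (see Details).
#' @return A list with numeric vectors `z` and `p`.
#' @export
ssn_statistic <- function(pcc_ref, delta_pcc, n_ref,
                          null = c("normal", "product")) {
  null <- match.arg(null)
  if (n_ref < 3) ssnet_error("n_ref must be >= 3", "ssnet_insufficient_reference_error")
  if (any(abs(pcc_ref) >= 1, na.rm = TRUE)) {
    ssnet_error("|pcc_ref| = 1: degenerate edge, statistic undefined",
                "ssnet_degenerate_edge_error")
  }
  z <- delta_pcc / ((1 - pcc_ref^2) / (n_ref - 1))
  p <- if (null == "normal") {
    2 * stats::pnorm(-abs(z))
  } else {
    normal_product_tail_interpolator()(z)
  }
  list(z = z, p = p)
}

#' Build the sample-specific network for one sample
#'
#' Appends the query sample to the reference cohort, recomputes each testable
#' edge's Pearson correlation over the `n_ref + 1` samples (incrementally,
#' from cached reference sufficient statistics), forms
#' `delta_pcc = pcc_perturbed - pcc_ref`, applies [ssn_statistic()], and
#' retains edges with `p < alpha`. The signed `delta_pcc` of retained edges is
#' preserved for downstream survival screening.
#'
#' @param refnet a `reference_network` from [compute_reference_pcc()].
#' @param sample a named numeric vector of expression values covering the
#'   network genes, or a one-column [expression_matrix()].
#' @param alpha significance level (default 0.05).
#' @param sample_id id recorded on the result (default: the vector/column
#'   name).
#' @param keep_all if `TRUE`, the full edge table (all testable edges, not
#'   just significant ones) is attached as `$all_edges`.
#' @param null null distribution for the statistic, passed to
#'   [ssn_statistic()]; default the canonical standard normal.
#' @param p_adjust per-sample multiple-testing correction applied across the
#'   testable edges before comparing to `alpha`: `"none"` (default),
#'   `"BH"` or any [stats::p.adjust()] method. Use together with
#'   `null = "product"`; adjusting the Gaussian p-values is not meaningful in
#'   the far tail.
#' @return An object of class `ssn`: list with `sample_id`, `alpha`,
#'   `n_tested`, and `edges` - a data.frame (`gene_a`, `gene_b`, `pcc_ref`,
#'   `pcc_perturbed`, `delta_pcc`, `z`, `p`, and `p_adj` when adjusted) of
#'   retained edges.
#' @export
build_ssn <- function(refnet, sample, alpha = 0.05, sample_id = NULL,
                      keep_all = FALSE, null = "normal", p_adjust = "none") {
  stopifnot(inherits(refnet, "reference_network"))
  if (is.null(refnet$stats)) {
    ssnet_error("run compute_reference_pcc() first", "ssnet_config_error")
  }
  if (inherits(sample, "expression_matrix")) {
    if (length(sample$sample_ids) != 1) {
      ssnet_error("build_ssn takes a single sample", "ssnet_alignment_error")
    }
    if (is.null(sample_id)) sample_id <- sample$sample_ids
    sample <- sample$values[, 1]
  }
  if (is.null(names(sample)) || !all(refnet$genes %in% names(sample))) {
    ssnet_error("sample vector must be named and cover all network genes",
                "ssnet_alignment_error")
  }
  x <- sample[refnet$genes]
  st <- refnet$stats
  n1 <- refnet$n_ref + 1L
  s1 <- st$sum + x
  q1 <- st$sumsq + x^2
  c1 <- st$cross + x[st$ia] * x[st$ib]
  var1 <- n1 * q1 - s1^2
  denom <- sqrt(pmax(var1[st$ia], 0) * pmax(var1[st$ib], 0))
  pcc1 <- ifelse(denom > 0, (n1 * c1 - s1[st$ia] * s1[st$ib]) / denom, NA_real_)
  pcc1 <- pmin(1, pmax(-1, pcc1))

  ok <- refnet$testable & !is.na(pcc1)
  delta <- pcc1 - refnet$pcc_ref
  stat <- ssn_statistic(refnet$pcc_ref[ok], delta[ok], refnet$n_ref, null = null)
  tab <- data.frame(
    gene_a = refnet$edges$gene_a[ok], gene_b = refnet$edges$gene_b[ok],
    pcc_ref = refnet$pcc_ref[ok], pcc_perturbed = pcc1[ok],
    delta_pcc = delta[ok], z = stat$z, p = stat$p,
    stringsAsFactors = FALSE)
  p_cmp <- if (p_adjust == "none") tab$p else {
    tab$p_adj <- stats::p.adjust(tab$p, method = p_adjust)
    tab$p_adj
  }
  kept <- tab[p_cmp < alpha, , drop = FALSE]
  rownames(kept) <- NULL
  out <- structure(list(sample_id = sample_id %||% "sample",
                        alpha = alpha, n_tested = sum(ok), edges = kept),
                   class = "ssn")
  if (keep_all) out$all_edges <- tab
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ssn <- function(x, ...) {
  cat(sprintf("ssn[%s]: %d significant of %d testable edges (alpha = %g)\n",
              x$sample_id, nrow(x$edges), x$n_tested, x$alpha))
  invisible(x)
}

#' Build SSNs for every sample of an expression matrix
#'
#' @param expr an [expression_matrix()] (tumor and/or normal samples).
#' @param refnet a `reference_network` from [compute_reference_pcc()].
#' @param alpha per-edge significance level.
#' @param samples optional subset of sample ids (default: all columns).
#' @param leave_one_out if `TRUE`, a sample that is itself part of the
#'   reference cohort is removed from the reference before its own SSN is
#'   built. Off by default: the reference stays the full normal cohort for
#'   every sample, normals included.
#' @inheritParams build_ssn
#' @return A named list of `ssn` objects.
#' @export
build_all_ssns <- function(expr, refnet, alpha = 0.05, samples = NULL,
                           leave_one_out = FALSE, null = "normal",
                           p_adjust = "none") {
  stopifnot(inherits(expr, "expression_matrix"))
  samples <- samples %||% expr$sample_ids
  ref_ids <- colnames(refnet$ref_values)
  out <- lapply(samples, function(sid) {
    rn <- refnet
    if (leave_one_out && sid %in% ref_ids) {
      keep <- setdiff(ref_ids, sid)
      ref_expr <- expression_matrix(refnet$ref_values[, keep, drop = FALSE],
                                    rep("normal", length(keep)))
      skeleton <- structure(list(edges = refnet$edges, genes = refnet$genes,
                                 pcc_ref = NULL, n_ref = NA_integer_),
                            class = "reference_network")
      rn <- compute_reference_pcc(skeleton, ref_expr)
    }
    build_ssn(rn, expr$values[, sid], alpha = alpha, sample_id = sid,
              null = null, p_adjust = p_adjust)
  })
  names(out) <- samples
  out
}

#' Run the full functional-network pipeline on a tumor/normal cohort
#'
#' Convenience wrapper: expression filter, background restriction, reference
#' correlations, SSNs for every sample, normal-edge subtraction, and
#' frequency aggregation into the functional network.
#'
#' The per-edge defaults here differ from the single-sample defaults of
#' [build_ssn()]: cohort-level aggregation subtracts the union of all
#' normal-sample SSN edges, so the per-edge false-positive rate of the
#' normal SSNs is amplified by the number of normal samples - with `n`
#' normals, a fraction `1 - (1 - q)^n` of edges is deleted, where `q` is the
#' per-edge retention under the null. The wrapper therefore uses the
#' tail-calibrated product null with per-sample Benjamini-Hochberg
#' correction, which drives `q` low enough for consistently perturbed tumor
#' edges to survive the subtraction, while single-sample analysis at a
#' nominal level keeps the canonical uncorrected statistic.
#'
#' @param expr combined tumor/normal [expression_matrix()].
#' @param background a [scored_edge_list()] (already score-filtered).
#' @param min_fraction expressed-fraction filter (default 0.5).
#' @param alpha per-sample significance level.
#' @param null,p_adjust passed to [build_ssn()]; defaults `"product"` and
#'   `"BH"` (see Details).
#' @param freq_threshold tumor-SSN frequency threshold (default 0.9).
#' @param degree_core degree threshold for core genes (default 3).
#' @return A list: `expr` (filtered), `refnet`, `ssns` (all samples),
#'   `specific` (tumor-specific SSNs), `functional_net`, `core_genes`.
#' @export
ssn_functional_pipeline <- function(expr, background, min_fraction = 0.5,
                                    alpha = 0.05, null = "product",
                                    p_adjust = "BH", freq_threshold = 0.9,
                                    degree_core = 3) {
  expr <- filter_expressed_genes(expr, min_fraction)
  normal_ids <- names(expr$sample_class)[expr$sample_class == "normal"]
  tumor_ids <- names(expr$sample_class)[expr$sample_class == "tumor"]
  ref_expr <- subset_expression(expr, samples = normal_ids)
  refnet <- compute_reference_pcc(build_background(background, expr), ref_expr)
  ssns <- build_all_ssns(expr, refnet, alpha = alpha, null = null,
                         p_adjust = p_adjust)
  specific <- lapply(ssns[tumor_ids], tumor_specific_ssn,
                     normal_ssns = ssns[normal_ids])
  fn <- aggregate_functional_network(specific, freq_threshold)
  list(expr = expr, refnet = refnet, ssns = ssns, specific = specific,
       functional_net = fn, core_genes = core_genes(fn, degree_core))
}

#' Write one SSN edge table per sample
#'
#' @param ssns named list of `ssn` objects.
#' @param dir output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_ssns <- function(ssns, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in ssns) {
    write_tsv_with_header(s$edges, file.path(dir, paste0(s$sample_id, ".tsv")),
                          params = list(sample = s$sample_id, alpha = s$alpha))
  }
  invisible(dir)
}
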