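# Consensus-clustering subtyping of tumor samples on core-gene expression,
# one-vs-rest representative DEG signatures, subtype-feature association and
# subtype survival curves.

#' Consensus clustering of tumor samples
#'
#' Repeats, for `iterations` rounds: subsample `floor(subsample_fraction *
#' m)` tumors without replacement, cluster them by agglomerative Ward linkage
#' on distance `1 - Pearson correlation` between samples, and cut at each
#' `k`. The consensus matrix entry for a pair is (times co-clustered) /
#' (times co-sampled); pairs never co-sampled are `NA` and counted in
#' `n_never_cosampled`. The final assignment at each `k` clusters
#' `1 - consensus` with average linkage and cuts at `k`.
#'
#' @param expr_core_tumors [expression_matrix()] of tumor samples restricted
#'   to the clustering panel (e.g. core functional genes).
#' @param k_range integer vector of cluster numbers (default `2:10`).
#' @param iterations resampling rounds (default 1000).
#' @param subsample_fraction fraction of samples drawn each round (default
#'   0.8).
#' @param seed integer seed.
#' @param scale_genes if `TRUE` (default), z-score genes before computing
#'   sample correlations. Row standardization is the canonical preprocessing
#'   for consensus clustering of expression panels: with heterogeneous gene
#'   abundances, unstandardized sample-sample correlation is dominated by
#'   abundance noise rather than subtype structure. Set `FALSE` to cluster
#'   on raw values.
#' @param store_log if `TRUE`, keep each round's sampled ids and cluster
#'   labels (for independent re-tallies); memory grows with `iterations`.
#' @return A named list (`"k2"`, `"k3"`, ...) of `consensus_result` objects:
#'   `k`, `consensus` (samples x samples), `assignments` (named vector),
#'   `iterations`, `subsample_fraction`, `seed`, `n_never_cosampled`, and
#'   optionally `log`.
#' @export
consensus_cluster <- function(expr_core_tumors, k_range = 2:10,
                              iterations = 1000, subsample_fraction = 0.8,
                              seed = 1L, scale_genes = TRUE,
                              store_log = FALSE) {
  stopifnot(inherits(expr_core_tumors, "expression_matrix"))
  ids <- expr_core_tumors$sample_ids
  m <- length(ids)
  if (iterations < 1) ssnet_error("iterations must be >= 1", "ssnet_config_error")
  if (m < max(k_range)) {
    ssnet_error("fewer samples than max(k_range)", "ssnet_config_error")
  }
  n_sub <- floor(subsample_fraction * m)
  if (n_sub < max(k_range)) {
    ssnet_error("subsample smaller than the largest k", "ssnet_config_error")
  }
  vals <- expr_core_tumors$values
  if (scale_genes) {
    vals <- t(scale(t(vals)))
    vals <- vals[apply(is.finite(vals), 1, all), , drop = FALSE]
  }
  co_sampled <- matrix(0L, m, m, dimnames = list(ids, ids))
  co_clustered <- lapply(k_range, function(k) co_sampled)
  names(co_clustered) <- as.character(k_range)
  log <- if (store_log) vector("list", iterations) else NULL

  with_sim_seed(seed, {
    for (it in seq_len(iterations)) {
      idx <- sort(sample.int(m, n_sub))
      d <- stats::as.dist(1 - stats::cor(vals[, idx, drop = FALSE]))
      hc <- stats::hclust(d, method = "ward.D2")
      cuts <- stats::cutree(hc, k = k_range)
      if (length(k_range) == 1) cuts <- matrix(cuts, ncol = 1)
      co_sampled[idx, idx] <- co_sampled[idx, idx] + 1L
      for (j in seq_along(k_range)) {
        cl <- cuts[, j]
        for (g in unique(cl)) {
          members <- idx[cl == g]
          co_clustered[[j]][members, members] <-
            co_clustered[[j]][members, members] + 1L
        }
      }
      if (store_log) {
        log[[it]] <- list(sampled = ids[idx],
                          labels = stats::setNames(
                            as.data.frame(cuts), paste0("k", k_range)))
      }
    }
  })

  out <- lapply(seq_along(k_range), function(j) {
    k <- k_range[j]
    cons <- ifelse(co_sampled > 0, co_clustered[[j]] / co_sampled, NA_real_)
    diag(cons) <- 1
    cons_filled <- cons
    cons_filled[is.na(cons_filled)] <- 0
    hc <- stats::hclust(stats::as.dist(1 - cons_filled), method = "average")
    assignments <- stats::cutree(hc, k = k)
    res <- list(k = k, consensus = cons,
                assignments = stats::setNames(assignments, ids),
                iterations = iterations,
                subsample_fraction = subsample_fraction, seed = seed,
                n_never_cosampled = sum(is.na(cons[upper.tri(cons)])))
    if (store_log) res$log <- log
    class(res) <- "consensus_result"
    res
  })
  names(out) <- paste0("k", k_range)
  out
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: k = %d, %d iterations at %.0f%% subsampling; cluster sizes: %s\n",
              x$k, x$iterations, 100 * x$subsample_fraction,
              paste(table(x$assignments), collapse = "/")))
  invisible(x)
}

row_t_test <- function(x, in_group, welch = TRUE) {
  n1 <- sum(in_group); n2 <- sum(!in_group)
  m1 <- rowMeans(x[, in_group, drop = FALSE])
  m2 <- rowMeans(x[, !in_group, drop = FALSE])
  v1 <- apply(x[, in_group, drop = FALSE], 1, stats::var)
  v2 <- apply(x[, !in_group, drop = FALSE], 1, stats::var)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(v1))
  }
  t <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(-abs(t), df)
  data.frame(gene = rownames(x), t = t, p = p, df = df,
             zero_var = (v1 == 0 & v2 == 0), stringsAsFactors = FALSE)
}

#' Representative DEGs per subtype
#'
#' For each subtype, a two-sided one-vs-rest t-test per gene (Welch by
#' default); the `top_n` lowest-p genes with positive t are the upregulated
#' signature, likewise for negative t. Genes selected by more than one
#' subtype are then dropped from every signature (uniqueness enforced after
#' selection). Genes with zero variance in both groups are skipped and
#' recorded.
#'
#' @param expr_tumors [expression_matrix()] of tumor samples (full gene set).
#' @param assignments named vector sample id -> subtype.
#' @param top_n genes per direction per subtype (default 100).
#' @param welch use the unequal-variance t-test (default `TRUE`).
#' @return A `subtype_signature`: list with `signatures` (per subtype, lists
#'   `up`/`down` of data.frames `gene`, `t`, `p`), `shared_dropped` (genes
#'   removed by the uniqueness filter), `skipped` (zero-variance genes).
#' @export
representative_degs <- function(expr_tumors, assignments, top_n = 100,
                                welch = TRUE) {
  stopifnot(inherits(expr_tumors, "expression_matrix"))
  assignments <- assignments[expr_tumors$sample_ids]
  if (anyNA(assignments)) {
    ssnet_error("assignments must cover all tumor samples", "ssnet_alignment_error")
  }
  subtypes <- sort(unique(assignments))
  if (any(table(assignments) < 2)) {
    ssnet_error("each subtype needs >= 2 samples", "ssnet_config_error")
  }
  x <- expr_tumors$values
  skipped <- character(0)
  raw <- lapply(subtypes, function(s) {
    tt <- row_t_test(x, assignments == s, welch = welch)
    skipped <<- union(skipped, tt$gene[tt$zero_var])
    tt <- tt[!tt$zero_var & is.finite(tt$t), ]
    up <- tt[tt$t > 0, ]; up <- up[order(up$p, up$gene), ]
    dn <- tt[tt$t < 0, ]; dn <- dn[order(dn$p, dn$gene), ]
    list(up = utils::head(up[, c("gene", "t", "p")], top_n),
         down = utils::head(dn[, c("gene", "t", "p")], top_n))
  })
  names(raw) <- as.character(subtypes)
  all_genes <- unlist(lapply(raw, function(r) c(r$up$gene, r$down$gene)))
  shared <- unique(all_genes[duplicated(all_genes)])
  signatures <- lapply(raw, function(r) {
    list(up = r$up[!(r$up$gene %in% shared), , drop = FALSE],
         down = r$down[!(r$down$gene %in% shared), , drop = FALSE])
  })
  structure(list(signatures = signatures, shared_dropped = shared,
                 skipped = skipped),
            class = "subtype_signature")
}

#' @export
print.subtype_signature <- function(x, ...) {
  for (s in names(x$signatures)) {
    cat(sprintf("subtype %s: %d up, %d down\n", s,
                nrow(x$signatures[[s]]$up), nrow(x$signatures[[s]]$down)))
  }
  if (length(x$shared_dropped)) {
    cat(sprintf("(%d shared genes dropped by uniqueness filter)\n",
                length(x$shared_dropped)))
  }
  invisible(x)
}

#' Association of subtypes with clinical/mutation/copy-number features
#'
#' For every categorical feature level and every subtype, a 2x2 Fisher exact
#' test of (level vs other levels) x (subtype vs rest). Clinical features are
#' the categorical confounders; mutations contribute one mutated/not feature
#' per gene; `cnv_flags` may add arbitrary logical features. Features with a
#' single observed level are skipped and recorded.
#'
#' @param assignments named vector sample id -> subtype.
#' @param clinical optional [clinical_table].
#' @param mutations optional `mutation_table`.
#' @param cnv_flags optional data.frame of logical columns, rownames =
#'   sample ids.
#' @param alpha significance flag threshold.
#' @return A data.frame (`feature`, `level`, `subtype`, `n11` ... `n22`,
#'   `odds_ratio`, `p`, `enriched`, `significant`) with attribute `skipped`.
#' @export
subtype_feature_association <- function(assignments, clinical = NULL,
                                        mutations = NULL, cnv_flags = NULL,
                                        alpha = 0.05) {
  ids <- names(assignments)
  features <- list()
  if (!is.null(clinical)) {
    cl <- clinical[match(ids, clinical$patient_id), ]
    for (col in c("sex", "pathologic_stage", "retrospective", "race",
                  "microsatellite_status")) {
      features[[col]] <- as.character(cl[[col]])
    }
  }
  if (!is.null(mutations) && nrow(mutations)) {
    for (g in unique(mutations$gene_id)) {
      mutated <- ids %in% mutations$sample_id[mutations$gene_id == g]
      features[[paste0("mut_", g)]] <- ifelse(mutated, "mutated", "wildtype")
    }
  }
  if (!is.null(cnv_flags)) {
    for (col in colnames(cnv_flags)) {
      features[[col]] <- ifelse(cnv_flags[match(ids, rownames(cnv_flags)), col],
                                "altered", "normal")
    }
  }
  if (!length(features)) ssnet_error("no features supplied", "ssnet_config_error")

  skipped <- character(0)
  rows <- list()
  for (fname in names(features)) {
    f <- features[[fname]]
    levels_obs <- sort(unique(f[!is.na(f)]))
    if (length(levels_obs) < 2) {
      skipped <- c(skipped, fname)
      next
    }
    for (lv in levels_obs) {
      for (s in sort(unique(assignments))) {
        ok <- !is.na(f)
        a <- sum(f[ok] == lv & assignments[ok] == s)
        b <- sum(f[ok] != lv & assignments[ok] == s)
        cc <- sum(f[ok] == lv & assignments[ok] != s)
        d <- sum(f[ok] != lv & assignments[ok] != s)
        ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))
        rows[[length(rows) + 1]] <- data.frame(
          feature = fname, level = lv, subtype = s,
          n11 = a, n12 = b, n21 = cc, n22 = d,
          odds_ratio = unname(ft$estimate), p = ft$p.value,
          enriched = unname(ft$estimate) > 1,
          significant = ft$p.value < alpha,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Survival differences between subtypes
#'
#' Multi-group log-rank test across the subtype assignment plus per-subtype
#' Kaplan-Meier curves exported as step functions.
#'
#' @param assignments named vector sample id -> subtype.
#' @param clinical a [clinical_table] (patients matched by `patient_id`).
#' @return A list: `chisq`, `df`, `p` (log-rank), `n`, `km` (data.frame
#'   `subtype`, `time`, `surv`, `n_risk`, `n_event`).
#' @export
subtype_survival <- function(assignments, clinical) {
  common <- intersect(names(assignments), clinical$patient_id)
  if (length(common) < 2) ssnet_error("no matching patients", "ssnet_alignment_error")
  cl <- clinical[match(common, clinical$patient_id), ]
  grp <- factor(assignments[common])
  ok <- !is.na(cl$survival_time) & !is.na(cl$event)
  cl <- cl[ok, ]; grp <- droplevels(grp[ok])
  if (nlevels(grp) < 2) ssnet_error("need >= 2 subtypes with outcome data", "ssnet_config_error")
  if (sum(cl$event) == 0) ssnet_error("no events: log-rank undefined", "ssnet_degenerate_test_error")
  sd <- survival::survdiff(survival::Surv(cl$survival_time, cl$event) ~ grp)
  df <- nlevels(grp) - 1
  fit <- survival::survfit(survival::Surv(cl$survival_time, cl$event) ~ grp)
  strata_id <- rep(sub("^grp=", "", names(fit$strata)), fit$strata)
  km <- data.frame(subtype = strata_id, time = fit$time, surv = fit$surv,
                   n_risk = fit$n.risk, n_event = fit$n.event,
                   stringsAsFactors = FALSE)
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(unname(sd$chisq), df, lower.tail = FALSE),
       n = nrow(cl), km = km)
}
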