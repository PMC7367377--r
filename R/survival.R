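# Prognostic screening of functional genes (expression) and functional
# edges (per-sample differential correlation): median split, Kaplan-Meier /
# log-rank, univariate and confounder-adjusted Cox, LASSO-Cox selection.

#' Median split of marker values
#'
#' Low group = values <= median, high group = values > median (ties at the
#' median go to the low group). Errors if every value is identical.
#'
#' @param values named numeric vector (names = patient ids).
#' @return A `survival_group_split`: list with `group` (named factor
#'   low/high) and `split_value` (the median).
#' @export
median_split <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) ssnet_error("need >= 2 observed values", "ssnet_config_error")
  med <- stats::median(values)
  if (all(values == values[1])) {
    ssnet_error("all marker values identical: degenerate split", "ssnet_degenerate_split_error")
  }
  grp <- factor(ifelse(values <= med, "low", "high"), levels = c("low", "high"))
  if (any(table(grp) == 0)) {
    ssnet_error("median split left one group empty", "ssnet_degenerate_split_error")
  }
  structure(list(group = stats::setNames(grp, names(values)), split_value = med),
            class = "survival_group_split")
}

#' Log-rank test between survival groups
#'
#' Standard observed-minus-expected log-rank chi-square with hypergeometric
#' variance at each distinct event time; p from chi-square with
#' (groups - 1) degrees of freedom.
#'
#' @param times survival times.
#' @param events event indicators (1 = event, 0 = censored).
#' @param groups group labels (>= 2 nonempty groups, >= 1 event overall).
#' @return A list with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2) ssnet_error("need >= 2 nonempty groups", "ssnet_config_error")
  if (sum(events) < 1) ssnet_error("no events: log-rank undefined", "ssnet_degenerate_test_error")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(unname(sd$chisq), df, lower.tail = FALSE))
}

prepare_confounders <- function(clinical, confounders) {
  df <- clinical[, confounders, drop = FALSE]
  for (col in confounders) {
    v <- df[[col]]
    if (col %in% c("year_of_diagnosis", "age_at_diagnosis")) {
      df[[col]] <- as.numeric(v)
    } else {
      f <- factor(v)
      if (nlevels(f) > 1) {
        ref <- names(which.max(table(f)))
        f <- stats::relevel(f, ref = ref)
      }
      df[[col]] <- f
    }
  }
  df
}

fit_cox <- function(data, formula) {
  converged <- TRUE
  fit <- withCallingHandlers(
    tryCatch(survival::coxph(formula, data = data),
             error = function(e) { converged <<- FALSE; NULL }),
    warning = function(w) {
      if (grepl("converge|infinite|singular|loglik", conditionMessage(w))) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    })
  list(fit = fit, converged = converged)
}

#' Univariate Cox regression on a median-split marker
#'
#' Proportional-hazards partial-likelihood fit with a single covariate: the
#' high/low indicator from [median_split()] (or the continuous marker value
#' with `binary = FALSE`). Reports the Wald p-value. Non-convergence is
#' returned as a flagged result, not an error.
#'
#' @param marker_values named numeric vector, names = patient ids.
#' @param clinical a [clinical_table].
#' @param binary dichotomize at the median (default `TRUE`).
#' @return A list: `beta`, `hr`, `p`, `n`, `n_events`, `converged`.
#' @export
cox_univariate <- function(marker_values, clinical, binary = TRUE) {
  common <- intersect(names(marker_values), clinical$patient_id)
  cl <- clinical[match(common, clinical$patient_id), ]
  mv <- marker_values[common]
  ok <- !is.na(cl$survival_time) & !is.na(cl$event) & !is.na(mv)
  cl <- cl[ok, ]; mv <- mv[ok]
  if (sum(cl$event) < 1) ssnet_error("no events", "ssnet_degenerate_test_error")
  if (length(unique(mv)) < 2) {
    ssnet_error("marker constant: no contrast", "ssnet_degenerate_split_error")
  }
  marker <- if (binary) median_split(mv)$group else as.numeric(mv)
  d <- data.frame(time = cl$survival_time, event = cl$event, marker = marker)
  res <- fit_cox(d, survival::Surv(time, event) ~ marker)
  if (is.null(res$fit)) {
    return(list(beta = NA_real_, hr = NA_real_, p = NA_real_,
                n = nrow(d), n_events = sum(d$event), converged = FALSE))
  }
  s <- summary(res$fit)
  list(beta = unname(stats::coef(res$fit)[1]),
       hr = unname(exp(stats::coef(res$fit)[1])),
       p = unname(s$coefficients[1, "Pr(>|z|)"]),
       n = nrow(d), n_events = sum(d$event), converged = res$converged)
}

#' Multivariate (confounder-adjusted) Cox regression
#'
#' Fits marker + confounders on complete cases (no imputation); categorical
#' confounders are dummy-coded with the most frequent level as reference.
#' Reports the marker's adjusted Wald p-value. Confounders that are constant
#' on the complete cases are dropped.
#'
#' @inheritParams cox_univariate
#' @param confounders clinical columns to adjust for (default: sex,
#'   pathologic stage, retrospective indicator, race, year of diagnosis, age
#'   at diagnosis, microsatellite status).
#' @return A list: `beta`, `hr`, `p`, `n`, `n_events`, `converged`,
#'   `confounders_used`.
#' @export
cox_multivariate <- function(marker_values, clinical,
                             confounders = CONFOUNDER_COLUMNS, binary = TRUE) {
  common <- intersect(names(marker_values), clinical$patient_id)
  cl <- clinical[match(common, clinical$patient_id), ]
  mv <- marker_values[common]
  conf <- prepare_confounders(cl, confounders)
  ok <- !is.na(cl$survival_time) & !is.na(cl$event) & !is.na(mv) &
    stats::complete.cases(conf)
  cl <- cl[ok, ]; mv <- mv[ok]; conf <- conf[ok, , drop = FALSE]
  if (sum(cl$event) < 1) ssnet_error("no events", "ssnet_degenerate_test_error")
  if (length(unique(mv)) < 2) {
    ssnet_error("marker constant on complete cases", "ssnet_degenerate_split_error")
  }
  keep <- vapply(conf, function(v) length(unique(v)) > 1, logical(1))
  conf <- conf[, keep, drop = FALSE]
  marker <- if (binary) median_split(mv)$group else as.numeric(mv)
  d <- data.frame(time = cl$survival_time, event = cl$event, marker = marker, conf)
  form <- stats::as.formula(paste("survival::Surv(time, event) ~ marker",
                                  if (ncol(conf)) paste("+", paste(colnames(conf), collapse = " + "))
                                  else ""))
  res <- fit_cox(d, form)
  if (is.null(res$fit)) {
    return(list(beta = NA_real_, hr = NA_real_, p = NA_real_, n = nrow(d),
                n_events = sum(d$event), converged = FALSE,
                confounders_used = colnames(conf)))
  }
  s <- summary(res$fit)
  i <- grep("^marker", rownames(s$coefficients))[1]
  list(beta = unname(s$coefficients[i, "coef"]),
       hr = unname(s$coefficients[i, "exp(coef)"]),
       p = unname(s$coefficients[i, "Pr(>|z|)"]),
       n = nrow(d), n_events = sum(d$event), converged = res$converged,
       confounders_used = colnames(conf))
}

#' Per-patient differential-correlation matrix for functional edges
#'
#' Edge-level marker values for survival screening: for each functional edge
#' and each sample, the signed `delta_pcc` of that edge in the sample's SSN,
#' or 0 if the edge is not in the SSN (not significant for that sample).
#'
#' @param functional_net a `functional_network`.
#' @param ssns named list of `ssn` objects (one per tumor sample).
#' @return Numeric matrix, edges (rows, named `geneA|geneB`) x samples.
#' @export
edge_delta_matrix <- function(functional_net, ssns) {
  keys <- edge_key(functional_net$edges$gene_a, functional_net$edges$gene_b)
  out <- matrix(0, length(keys), length(ssns),
                dimnames = list(keys, names(ssns)))
  for (sid in names(ssns)) {
    e <- ssns[[sid]]$edges
    if (!nrow(e)) next
    ek <- edge_key(e$gene_a, e$gene_b)
    hit <- match(keys, ek)
    found <- !is.na(hit)
    out[found, sid] <- e$delta_pcc[hit[found]]
  }
  out
}

screen_one <- function(values, clinical, alpha) {
  res <- list(logrank_p = NA_real_, uni_beta = NA_real_, uni_hr = NA_real_,
              uni_p = NA_real_, multi_beta = NA_real_, multi_hr = NA_real_,
              multi_p = NA_real_, converged = FALSE)
  ok <- tryCatch({
    split <- median_split(values[!is.na(values)])
    common <- intersect(names(split$group), clinical$patient_id)
    cl <- clinical[match(common, clinical$patient_id), ]
    use <- !is.na(cl$survival_time) & !is.na(cl$event)
    lr <- logrank_test(cl$survival_time[use], cl$event[use],
                       split$group[common][use])
    res$logrank_p <- lr$p
    uni <- cox_univariate(values, clinical)
    res[c("uni_beta", "uni_hr", "uni_p")] <- uni[c("beta", "hr", "p")]
    multi <- cox_multivariate(values, clinical)
    res[c("multi_beta", "multi_hr", "multi_p")] <- multi[c("beta", "hr", "p")]
    res$converged <- isTRUE(uni$converged) && isTRUE(multi$converged)
    TRUE
  }, ssnet_error = function(e) FALSE)
  res$ok <- ok
  res
}

#' Screen functional genes and edges as prognosis biomarkers
#'
#' Applies, to every functional gene (expression) and every functional edge
#' (per-sample signed `delta_pcc`, zero when absent from the SSN): a median
#' split, the log-rank test, univariate Cox, and confounder-adjusted
#' multivariate Cox on complete cases. A marker passes when both Cox p-values
#' are below `alpha`. No multiple-testing correction by default; set
#' `p_adjust = "BH"` to adjust the Cox p-values across markers before the
#' pass flag is computed.
#'
#' @param functional_net a `functional_network`.
#' @param ssns named list of tumor `ssn` objects (for the edge markers); may
#'   be `NULL` to screen genes only.
#' @param expr [expression_matrix()] containing the functional genes and the
#'   screened patients' samples.
#' @param clinical a [clinical_table]; patient ids must match sample ids.
#' @param alpha significance level (default 0.05).
#' @param p_adjust `"none"` (default) or a [stats::p.adjust()] method.
#' @return A data.frame, one row per marker: `marker`, `kind` (gene/edge),
#'   `logrank_p`, `uni_*`, `multi_*`, `converged`, `passes`.
#' @export
screen_biomarkers <- function(functional_net, ssns, expr, clinical,
                              alpha = 0.05, p_adjust = "none") {
  stopifnot(inherits(functional_net, "functional_network"),
            inherits(expr, "expression_matrix"))
  markers <- list()
  for (g in functional_net$genes) {
    markers[[g]] <- list(kind = "gene", values = expr$values[g, ])
  }
  if (!is.null(ssns) && length(ssns)) {
    dm <- edge_delta_matrix(functional_net, ssns)
    for (k in rownames(dm)) {
      markers[[k]] <- list(kind = "edge", values = dm[k, ])
    }
  }
  rows <- lapply(names(markers), function(nm) {
    r <- screen_one(markers[[nm]]$values, clinical, alpha)
    data.frame(marker = nm, kind = markers[[nm]]$kind,
               logrank_p = r$logrank_p,
               uni_beta = r$uni_beta, uni_hr = r$uni_hr, uni_p = r$uni_p,
               multi_beta = r$multi_beta, multi_hr = r$multi_hr,
               multi_p = r$multi_p, converged = r$converged, ok = r$ok,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (p_adjust != "none") {
    out$uni_p <- stats::p.adjust(out$uni_p, method = p_adjust)
    out$multi_p <- stats::p.adjust(out$multi_p, method = p_adjust)
  }
  out$passes <- out$ok & out$converged &
    !is.na(out$uni_p) & !is.na(out$multi_p) &
    out$uni_p < alpha & out$multi_p < alpha
  out$ok <- NULL
  out
}

#' LASSO-Cox selection of a joint marker panel
#'
#' L1-penalized Cox path over the candidate markers; the penalty is chosen by
#' 10-fold cross-validated partial-likelihood deviance at its minimum. An
#' unpenalized Cox model is then refit on the selected markers and the joint
#' likelihood-ratio p-value reported.
#'
#' @param markers numeric matrix, patients (rows, named) x candidate markers
#'   (columns, >= 2).
#' @param clinical a [clinical_table].
#' @param seed integer seed for the CV fold assignment.
#' @param nfolds CV folds (default 10).
#' @return A list: `selected` (marker names; possibly empty), `coefficients`
#'   (penalized, at the chosen lambda), `lambda`, `joint_p` (likelihood-ratio
#'   p of the refit; `NA` when nothing selected), `refit` (the `coxph` fit or
#'   `NULL`).
#' @export
lasso_cox_select <- function(markers, clinical, seed = 1L, nfolds = 10) {
  if (is.null(dim(markers)) || ncol(markers) < 2) {
    ssnet_error("need >= 2 candidate markers", "ssnet_config_error")
  }
  common <- intersect(rownames(markers), clinical$patient_id)
  cl <- clinical[match(common, clinical$patient_id), ]
  x <- markers[common, , drop = FALSE]
  ok <- !is.na(cl$survival_time) & !is.na(cl$event) & cl$survival_time > 0 &
    stats::complete.cases(x)
  cl <- cl[ok, ]; x <- x[ok, , drop = FALSE]
  if (sum(cl$event) < 2) ssnet_error("too few events for LASSO-Cox", "ssnet_degenerate_test_error")
  y <- survival::Surv(cl$survival_time, cl$event)
  cvfit <- with_sim_seed(seed, {
    foldid <- sample(rep_len(seq_len(nfolds), nrow(x)))
    glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid)
  })
  coefs <- as.matrix(stats::coef(cvfit, s = "lambda.min"))[, 1]
  selected <- names(coefs)[coefs != 0]
  if (!length(selected)) {
    message("LASSO-Cox selected no markers at lambda.min")
    return(list(selected = character(0), coefficients = coefs,
                lambda = cvfit$lambda.min, joint_p = NA_real_, refit = NULL))
  }
  d <- data.frame(time = cl$survival_time, event = cl$event,
                  x[, selected, drop = FALSE], check.names = FALSE)
  form <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                  paste(sprintf("`%s`", selected), collapse = " + ")))
  refit <- survival::coxph(form, data = d)
  s <- summary(refit)
  list(selected = selected, coefficients = coefs, lambda = cvfit$lambda.min,
       joint_p = unname(s$logtest["pvalue"]), refit = refit)
}
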