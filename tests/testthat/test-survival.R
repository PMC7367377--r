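test_that("median split follows the low-inclusive tie rule", {
  s1 <- median_split(setNames(c(1, 2, 3, 4), paste0("p", 1:4)))
  expect_equal(unname(s1$group[c("p1", "p2")]), factor(c("low", "low"), levels = c("low", "high")))
  expect_equal(as.character(s1$group[c("p3", "p4")]), c("high", "high"))
  expect_equal(s1$split_value, 2.5)

  s2 <- median_split(setNames(c(1, 2, 2, 5), paste0("p", 1:4)))
  expect_equal(as.character(s2$group), c("low", "low", "low", "high"))

  expect_error(median_split(setNames(rep(3, 4), paste0("p", 1:4))),
               class = "ssnet_degenerate_split_error")

  # group sizes differ by at most the number of values tied at the median
  set.seed(70)
  v <- setNames(sample(1:8, 30, replace = TRUE), paste0("p", 1:30))
  sp <- median_split(v)
  ties <- sum(v == median(v))
  expect_lte(abs(sum(sp$group == "low") - sum(sp$group == "high")), ties)
})

test_that("log-rank is zero on mirrored groups and matches the hand example", {
  # identical event-time patterns in both groups
  t_ <- c(1, 2, 3, 4, 1, 2, 3, 4)
  g <- rep(c("A", "B"), each = 4)
  lr0 <- logrank_test(t_, rep(1, 8), g)
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-12)

  # group A events at t=1,2; group B at t=3,4; O=2, E=5/6, V=0.4722
  lr <- logrank_test(c(1, 2, 3, 4), rep(1, 4), c("A", "A", "B", "B"))
  expect_equal(lr$chisq, 2.8823529, tolerance = 1e-6)
  expect_equal(lr$df, 1L)

  expect_error(logrank_test(c(1, 2), c(1, 1), c("A", "A")),
               class = "ssnet_config_error")
  expect_error(logrank_test(c(1, 2), c(0, 0), c("A", "B")),
               class = "ssnet_degenerate_test_error")
})

test_that("log-rank p-values are uniform under label permutation", {
  set.seed(71)
  n <- 60
  time <- rexp(n, 1 / 300)
  event <- rbinom(n, 1, 0.8)
  ps <- vapply(1:400, function(i) {
    g <- sample(rep(c("A", "B"), each = n / 2))
    logrank_test(time, event, g)$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_gt(mean(ps < 0.05) , 0.01)
  expect_lt(mean(ps < 0.05) , 0.12)
})

test_that("univariate Cox recovers a planted log-hazard and calibrates under the null", {
  cfg <- sim_config(n_genes = 60, n_normal = 10, n_tumor = 300,
                    censoring_rate = 0.3, n_subtypes = 2, n_subtype_genes = 5,
                    hazard_genes = c(g0010 = 1), seed = 72)
  ref <- generate_reference_expression(cfg)
  tum <- generate_tumor_samples(cfg, ref)
  cl <- generate_survival(cfg, tum)
  marker <- scale(tum$values["g0010", ])[, 1]
  names(marker) <- tum$sample_ids
  fit <- cox_univariate(marker, cl, binary = FALSE)
  expect_lt(abs(fit$beta - 1), 0.3)
  expect_true(fit$converged)

  # type-I error of the binary screen on a survival-independent marker
  set.seed(73)
  rejections <- vapply(1:150, function(i) {
    m <- setNames(rnorm(length(cl$patient_id)), cl$patient_id)
    cox_univariate(m, cl)$p < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.01)
  expect_lt(mean(rejections), 0.11)

  expect_error(cox_univariate(setNames(rep(1, 300), cl$patient_id), cl),
               class = "ssnet_degenerate_split_error")
})

test_that("multivariate Cox matches univariate without confounding and controls planted confounding", {
  cfg <- sim_config(n_genes = 60, n_normal = 10, n_tumor = 250,
                    censoring_rate = 0.3, clinical_missing_rate = 0,
                    n_subtypes = 2, n_subtype_genes = 5,
                    hazard_genes = c(g0010 = 1), seed = 74)
  ref <- generate_reference_expression(cfg)
  tum <- generate_tumor_samples(cfg, ref)
  cl <- generate_survival(cfg, tum)
  marker <- setNames(tum$values["g0010", ], tum$sample_ids)
  uni <- cox_univariate(marker, cl)
  multi <- cox_multivariate(marker, cl)
  expect_lt(abs(multi$beta - uni$beta), 0.35)

  # stage drives both the marker distribution and the hazard; the marker has
  # no direct effect, so adjustment should remove the association
  cfg2 <- sim_config(n_genes = 60, n_normal = 10, n_tumor = 400,
                     censoring_rate = 0.2, clinical_missing_rate = 0,
                     confound_survival = TRUE,
                     n_subtypes = 2, n_subtype_genes = 5,
                     hazard_genes = c(g0010 = 0), seed = 75)
  ref2 <- generate_reference_expression(cfg2)
  tum2 <- generate_tumor_samples(cfg2, ref2)
  cl2 <- generate_survival(cfg2, tum2)
  marker2 <- setNames(tum2$values["g0010", ], tum2$sample_ids)
  uni2 <- cox_univariate(marker2, cl2)
  multi2 <- cox_multivariate(marker2, cl2, confounders = "pathologic_stage")
  expect_lt(uni2$p, 0.05)
  expect_gt(multi2$p, 0.05)
})

test_that("biomarker screening recovers planted prognostic genes with a calibrated false rate", {
  cfg <- sim_config(n_genes = 80, n_normal = 30, n_tumor = 200,
                    censoring_rate = 0.4, clinical_missing_rate = 0,
                    n_subtypes = 2, n_subtype_genes = 5,
                    hazard_genes = c(g0011 = 1.2, g0012 = -1.2, g0013 = 1.2),
                    n_planted = 5, seed = 76)
  sim <- simulate_cohort(cfg)
  # screen a gene panel containing the hazard genes
  fn <- structure(list(
    edges = data.frame(gene_a = character(0), gene_b = character(0),
                       frequency = numeric(0)),
    genes = sprintf("g%04d", 1:40), degree = integer(0),
    n_tumors = 200, freq_threshold = 0.9), class = "functional_network")
  res <- screen_biomarkers(fn, NULL, sim$tumor, sim$clinical)
  expect_equal(nrow(res), 40L)
  planted <- c("g0011", "g0012", "g0013")
  expect_true(all(res$passes[res$marker %in% planted]))
  expect_lte(mean(res$passes[!(res$marker %in% planted)]), 0.15)
  # pass flag is exactly the conjunction of the two Cox tests
  expect_equal(res$passes,
               res$converged & !is.na(res$uni_p) & !is.na(res$multi_p) &
                 res$uni_p < 0.05 & res$multi_p < 0.05)
  # planted directions: positive beta for the high group of a +1 gene
  expect_gt(res$uni_hr[res$marker == "g0011"], 1)
  expect_lt(res$uni_hr[res$marker == "g0012"], 1)
})

test_that("edge markers take signed delta_pcc with zero for absent edges", {
  ssns <- list(
    s1 = ssn_stub("s1", list(c("a", "b"))),
    s2 = ssn_stub("s2", list()))
  ssns$s1$edges$delta_pcc <- -0.25
  fn <- structure(list(
    edges = data.frame(gene_a = c("a", "c"), gene_b = c("b", "d"),
                       frequency = c(0.95, 0.95)),
    genes = c("a", "b", "c", "d"),
    degree = setNames(rep(1L, 4), c("a", "b", "c", "d")),
    n_tumors = 2, freq_threshold = 0.9), class = "functional_network")
  dm <- edge_delta_matrix(fn, ssns)
  expect_equal(dm["a|b", "s1"], -0.25)
  expect_equal(dm["a|b", "s2"], 0)
  expect_equal(unname(dm["c|d", ]), c(0, 0))
})

test_that("LASSO-Cox keeps a strong marker and stays sparse under the null", {
  set.seed(77)
  n <- 200
  ids <- sprintf("p%03d", 1:n)
  x <- matrix(rnorm(n * 10), n, 10, dimnames = list(ids, paste0("m", 1:10)))
  lp <- 1.2 * x[, 1]
  time <- rexp(n, exp(lp) / 400)
  cens <- rexp(n, 1 / 800)
  cl <- validate_clinical(data.frame(
    patient_id = ids, survival_time = round(pmin(time, cens), 1) + 0.1,
    event = as.integer(time <= cens), stringsAsFactors = FALSE))
  hits <- vapply(1:5, function(s) {
    "m1" %in% lasso_cox_select(x, cl, seed = s)$selected
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  sel <- lasso_cox_select(x, cl, seed = 1)
  expect_lt(sel$joint_p, 0.01)

  # all-null markers: median selection size stays small
  sizes <- vapply(1:6, function(s) {
    set.seed(300 + s)
    xn <- matrix(rnorm(n * 10), n, 10, dimnames = list(ids, paste0("m", 1:10)))
    tn <- rexp(n, 1 / 400)
    cl_n <- validate_clinical(data.frame(
      patient_id = ids, survival_time = round(pmin(tn, cens), 1) + 0.1,
      event = as.integer(tn <= cens), stringsAsFactors = FALSE))
    suppressMessages(length(lasso_cox_select(xn, cl_n, seed = s)$selected))
  }, numeric(1))
  expect_lte(median(sizes), 1)

  expect_error(lasso_cox_select(x[, 1, drop = FALSE], cl, seed = 1),
               class = "ssnet_config_error")
})

test_that("screening runs end-to-end on simulated genes and edges together", {
  sim <- simulate_cohort(sim_config(seed = 78, n_normal = 40,
                                    clinical_missing_rate = 0))
  pipe <- ssn_functional_pipeline(sim$expr, sim$background)
  tumor_ids <- sim$tumor$sample_ids
  res <- screen_biomarkers(pipe$functional_net, pipe$ssns[tumor_ids],
                           sim$tumor, sim$clinical)
  expect_setequal(unique(res$kind), c("gene", "edge"))
  expect_equal(sum(res$kind == "edge"), nrow(pipe$functional_net$edges))
  expect_true(all(res$passes %in% c(TRUE, FALSE)))
  # hazard genes that sit in the functional network must be detectable when
  # they are screened; at minimum the result table is internally consistent
  expect_true(all(is.na(res$uni_p) | (res$uni_p >= 0 & res$uni_p <= 1)))
  expect_true(all(is.na(res$multi_p) | (res$multi_p >= 0 & res$multi_p <= 1)))
})
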