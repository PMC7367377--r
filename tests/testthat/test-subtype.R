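test_that("consensus clustering resolves duplicated blobs into clean blocks", {
  set.seed(60)
  center1 <- rnorm(25); center2 <- rnorm(25) + 4
  vals <- cbind(
    sapply(1:10, function(i) center1 + rnorm(25, sd = 0.05)),
    sapply(1:10, function(i) center2 + rnorm(25, sd = 0.05)))
  dimnames(vals) <- list(sprintf("g%02d", 1:25), sprintf("t%02d", 1:20))
  expr <- expression_matrix(abs(vals) + 1, rep("tumor", 20))
  # raw values: the two blobs are separable without row standardization (a
  # two-level design degenerates under z-scoring, every gene sharing one
  # bimodal pattern)
  cons <- consensus_cluster(expr, k_range = 2, iterations = 50, seed = 1,
                            scale_genes = FALSE)$k2
  within <- c(cons$consensus[1:10, 1:10][upper.tri(diag(10))],
              cons$consensus[11:20, 11:20][upper.tri(diag(10))])
  between <- cons$consensus[1:10, 11:20]
  expect_true(all(within[!is.na(within)] > 0.95))
  expect_true(all(between[!is.na(between)] < 0.05))
  expect_equal(length(unique(cons$assignments[1:10])), 1L)
  expect_false(cons$assignments[1] == cons$assignments[11])
  # determinism
  cons2 <- consensus_cluster(expr, k_range = 2, iterations = 50, seed = 1,
                             scale_genes = FALSE)$k2
  expect_identical(cons$consensus, cons2$consensus)
})

test_that("consensus matrix equals a brute-force tally of the iteration log", {
  expr <- random_expression(15, 12, seed = 61, class = rep("tumor", 12))
  res <- consensus_cluster(expr, k_range = 3, iterations = 25, seed = 2,
                           store_log = TRUE)$k3
  ids <- expr$sample_ids
  co <- matrix(0, 12, 12, dimnames = list(ids, ids))
  tog <- matrix(0, 12, 12, dimnames = list(ids, ids))
  for (it in res$log) {
    s <- it$sampled
    tog[s, s] <- tog[s, s] + 1
    lab <- it$labels$k3
    for (g in unique(lab)) {
      m <- s[lab == g]
      co[m, m] <- co[m, m] + 1
    }
  }
  manual <- ifelse(tog > 0, co / tog, NA_real_)
  diag(manual) <- 1
  expect_equal(res$consensus, manual, tolerance = 1e-12)
  expect_true(isSymmetric(unname(ifelse(is.na(res$consensus), -1, res$consensus))))
  rng <- range(res$consensus, na.rm = TRUE)
  expect_gte(rng[1], 0); expect_lte(rng[2], 1)
})

test_that("planted six-subtype structure is recovered at k = 6", {
  sim <- simulate_cohort(sim_config(seed = 42))
  panel <- unlist(sim$truth$subtype_genes)
  cons <- consensus_cluster(subset_expression(sim$tumor, genes = panel),
                            k_range = 6, iterations = 200, seed = 5)$k6
  ari <- adjusted_rand(cons$assignments,
                       sim$truth$subtypes[names(cons$assignments)])
  expect_gte(ari, 0.9)
})

test_that("representative DEGs rank dominant shifts first and enforce uniqueness", {
  # 5 subtypes: g01 strongly up in subtype 1 only; each other subtype has
  # its own strongly down gene, so the diluted one-vs-rest echo of g01 never
  # tops another subtype's list and g01 survives the uniqueness filter
  set.seed(62)
  vals <- matrix(rnorm(40 * 40, 10), 40, 40,
                 dimnames = list(sprintf("g%02d", 1:40), sprintf("t%02d", 1:40)))
  assignments <- setNames(rep(1:5, each = 8), colnames(vals))
  for (s in 1:5) {
    up <- sprintf("g%02d", s); dn <- sprintf("g%02d", 10 + s)
    vals[up, assignments == s] <- vals[up, assignments == s] + 5
    vals[dn, assignments == s] <- vals[dn, assignments == s] - 5
  }
  expr <- expression_matrix(abs(vals), rep("tumor", 40))
  sig <- representative_degs(expr, assignments, top_n = 1)
  expect_equal(sig$signatures[["1"]]$up$gene[1], "g01")
  expect_equal(sig$signatures[["2"]]$down$gene[1], "g12")
  expect_false("g01" %in% sig$shared_dropped)
  # signs consistent
  for (s in names(sig$signatures)) {
    expect_true(all(sig$signatures[[s]]$up$t > 0))
    expect_true(all(sig$signatures[[s]]$down$t < 0))
  }
  # uniqueness: no gene in two subtypes' signatures
  all_genes <- unlist(lapply(sig$signatures, function(x) c(x$up$gene, x$down$gene)))
  expect_false(any(duplicated(all_genes)))
})

test_that("a gene top-ranked in two subtypes is dropped from both signatures", {
  set.seed(63)
  vals <- matrix(rnorm(20 * 30, 10), 20, 30,
                 dimnames = list(sprintf("g%02d", 1:20), sprintf("t%02d", 1:30)))
  assignments <- setNames(rep(1:3, each = 10), colnames(vals))
  # g01 strongly up in subtype 1 AND subtype 2 (vs rest): selected by both
  vals["g01", assignments != 3] <- vals["g01", assignments != 3] + 6
  expr <- expression_matrix(abs(vals), rep("tumor", 30))
  sig <- representative_degs(expr, assignments, top_n = 3)
  expect_true("g01" %in% sig$shared_dropped)
  for (s in c("1", "2")) {
    expect_false("g01" %in% sig$signatures[[s]]$up$gene)
  }
  # an identically distributed gene is never a dominant pick
  expect_false(sig$signatures[["3"]]$up$gene[1] %in% sig$shared_dropped)
})

test_that("feature association flags planted contingency and matches exact Fisher", {
  assignments <- setNames(rep(1:2, each = 10), sprintf("t%02d", 1:20))
  mut <- data.frame(
    sample_id = sprintf("t%02d", 1:10), gene_id = "G",
    variant_classification = "Missense_Mutation", variant_type = "SNP",
    stringsAsFactors = FALSE)
  class(mut) <- c("mutation_table", "data.frame")
  assoc <- subtype_feature_association(assignments, mutations = mut)
  hit <- assoc[assoc$level == "mutated" & assoc$subtype == 1, ]
  # 10/0 vs 0/10 table: exact Fisher p = 2 / C(20,10)
  expect_equal(hit$p, 2 / choose(20, 10), tolerance = 1e-10)
  expect_equal(hit$p, 1.08e-5, tolerance = 1e-2)
  expect_true(hit$significant && hit$enriched)
  # single-level features are skipped and logged
  cl <- validate_clinical(data.frame(
    patient_id = sprintf("t%02d", 1:20), survival_time = 100, event = 0,
    sex = "male", stringsAsFactors = FALSE))
  assoc2 <- subtype_feature_association(assignments, clinical = cl,
                                        mutations = mut)
  expect_true("sex" %in% attr(assoc2, "skipped"))
})

test_that("subtype survival detects a planted hazard difference and reduces to two-group log-rank", {
  set.seed(64)
  n <- 120
  grp <- setNames(rep(1:2, each = n / 2), sprintf("t%03d", 1:n))
  time <- c(rexp(n / 2, 1 / 500), rexp(n / 2, 5 / 500))
  cl <- validate_clinical(data.frame(
    patient_id = names(grp), survival_time = round(time, 1), event = 1,
    stringsAsFactors = FALSE))
  res <- subtype_survival(grp, cl)
  expect_lt(res$p, 0.01)
  # k = 2 multi-group statistic equals the two-group log-rank formula
  lr <- logrank_test(cl$survival_time, cl$event, grp)
  expect_equal(res$chisq, lr$chisq, tolerance = 1e-10)
  expect_equal(res$p, lr$p, tolerance = 1e-10)
  # KM export is a step function per subtype covering all event times
  expect_setequal(unique(res$km$subtype), c("1", "2"))
  expect_true(all(diff(res$km$surv[res$km$subtype == "1"]) <= 0))

  cl0 <- cl; cl0$event <- 0L
  expect_error(subtype_survival(grp, cl0), class = "ssnet_degenerate_test_error")
})

test_that("up-signatures of planted disjoint subtypes contain only planted genes", {
  sim <- simulate_cohort(sim_config(seed = 65))
  sig <- representative_degs(sim$tumor, sim$truth$subtypes, top_n = 10)
  for (s in names(sig$signatures)) {
    up <- sig$signatures[[s]]$up$gene
    if (length(up)) {
      expect_true(all(up %in% sim$truth$subtype_genes[[as.integer(s)]]))
    }
  }
  # pooled precision over all reported up genes
  all_up <- unlist(lapply(sig$signatures, function(x) x$up$gene))
  expect_gte(mean(all_up %in% unlist(sim$truth$subtype_genes)), 0.9)
})
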