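test_that("generators are fully deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 60, n_normal = 10, n_tumor = 20,
                    n_subtypes = 2, n_subtype_genes = 5, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$truth$planted_edges, b$truth$planted_edges)
})

test_that("reference samples hit the target edge correlation", {
  cfg <- sim_config(n_genes = 100, n_normal = 200, rho_ref = 0.7,
                    background_density = 0.008, seed = 2)
  ref <- generate_reference_expression(cfg)
  model <- attr(ref, "sim_model")
  ends <- ssnet:::split_edge_key(model$edge_keys)
  pcc <- mapply(function(a, b) cor(ref$values[a, ], ref$values[b, ]),
                ends$gene_a, ends$gene_b)
  expect_gte(mean(abs(pcc - 0.7) <= 0.1), 0.95)
})

test_that("rho_ref = 0 gives edge correlations with Fisher-z spread 1/sqrt(n-3)", {
  cfg <- sim_config(n_genes = 100, n_normal = 150, rho_ref = 0,
                    background_density = 0.02, seed = 4)
  ref <- generate_reference_expression(cfg)
  model <- attr(ref, "sim_model")
  ends <- ssnet:::split_edge_key(model$edge_keys)
  pcc <- mapply(function(a, b) cor(ref$values[a, ], ref$values[b, ]),
                ends$gene_a, ends$gene_b)
  ratio <- sd(atanh(pcc)) * sqrt(cfg$n_normal - 3)
  expect_gt(ratio, 0.75)
  expect_lt(ratio, 1.3)
  expect_lt(abs(mean(pcc)), 0.05)
})

test_that("delta = 0 makes tumors statistically exchangeable with normals", {
  cfg <- sim_config(n_genes = 150, n_normal = 40, n_tumor = 40, delta = 0,
                    subtype_effect = 0, seed = 5)
  ref <- generate_reference_expression(cfg)
  tum <- generate_tumor_samples(cfg, ref)
  pvals <- vapply(seq_len(nrow(ref$values)), function(i) {
    t.test(ref$values[i, ], tum$values[i, ])$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("planted_frequency = 1 with strong delta marks every tumor a carrier", {
  cfg <- sim_config(n_genes = 60, n_normal = 10, n_tumor = 15,
                    planted_frequency = 1, n_planted = 5,
                    n_subtypes = 3, n_subtype_genes = 4, seed = 6)
  ref <- generate_reference_expression(cfg)
  tum <- generate_tumor_samples(cfg, ref)
  carriers <- attr(tum, "carriers")
  expect_equal(length(carriers), 5L)
  for (who in carriers) expect_setequal(who, tum$sample_ids)
})

test_that("infeasible correlation structures are rejected with a diagnostic", {
  # a degree-2 hub at rho 0.7 needs 1.4 units of shared-factor variance
  star <- data.frame(a = c(1, 1), b = c(2, 3))
  cfg <- sim_config(n_genes = 10, n_normal = 5, rho_ref = 0.7,
                    background_edges = star, n_planted = 1,
                    n_subtypes = 2, n_subtype_genes = 2, seed = 1)
  expect_error(generate_reference_expression(cfg),
               class = "ssnet_generation_error")
  expect_error(
    sim_config(planted_frequency = 0),
    class = "ssnet_config_error")
})

test_that("survival generator obeys censoring settings and hazard directions", {
  cfg <- sim_config(n_genes = 60, n_normal = 10, n_tumor = 200,
                    censoring_rate = 0, n_subtypes = 2, n_subtype_genes = 5,
                    hazard_genes = c(g0005 = 1), seed = 8)
  ref <- generate_reference_expression(cfg)
  tum <- generate_tumor_samples(cfg, ref)
  cl <- generate_survival(cfg, tum)
  expect_true(all(cl$event == 1L))
  # beta = +1: high-expression group has worse survival (HR > 1)
  fit <- cox_univariate(tum$values["g0005", ], cl)
  expect_gt(fit$hr, 1)

  cfg_bad <- sim_config(n_genes = 60, n_normal = 10, n_tumor = 20,
                        censoring_rate = 1, n_subtypes = 2,
                        n_subtype_genes = 5,
                        hazard_genes = c(g0005 = 0), seed = 8)
  expect_error(generate_survival(cfg_bad, tum),
               class = "ssnet_generation_error")
})

test_that("generated gene sets have the constructed overlaps", {
  cfg <- sim_config(n_genes = 100, n_normal = 10, n_tumor = 10,
                    n_subtypes = 2, n_subtype_genes = 5, seed = 9)
  planted <- sprintf("g%04d", 1:12)
  gs <- generate_gene_sets(cfg, planted, set_sizes = c(30, 20),
                           overlaps = c(8, 0))
  expect_equal(gs$universe_size, 100L)
  expect_setequal(gs$sets$planted_exact, planted)
  expect_equal(length(intersect(gs$sets$overlap_k8_A30, planted)), 8L)
  expect_equal(length(intersect(gs$sets$overlap_k0_A20, planted)), 0L)
  # k = 0 construction gives p = 1 downstream
  er <- enrich_collection(planted, gs)
  expect_equal(er$p[er$set == "overlap_k0_A20"], 1)
  # the exact planted set has the smallest p in the collection
  expect_equal(er$set[which.min(er$p)], "planted_exact")
  expect_error(generate_gene_sets(cfg, planted, set_sizes = 5, overlaps = 6),
               class = "ssnet_config_error")
})

test_that("mutation generator links designated genes to subtype 1", {
  cfg <- sim_config(n_genes = 80, n_normal = 10, n_tumor = 120,
                    n_subtypes = 2, n_subtype_genes = 5, seed = 10)
  subtypes <- setNames(rep(1:2, each = 60), sprintf("T%03d", 1:120))
  mut <- generate_mutations(cfg, subtypes)
  elev <- attr(mut, "elevated_genes")
  assoc <- subtype_feature_association(subtypes, mutations = mut)
  hit <- assoc[assoc$feature == paste0("mut_", elev[1]) &
                 assoc$level == "mutated" & assoc$subtype == 1, ]
  expect_true(hit$enriched)
  expect_lt(hit$p, 0.01)

  cfg0 <- sim_config(n_genes = 80, n_normal = 10, n_tumor = 20,
                     n_subtypes = 2, n_subtype_genes = 5,
                     mutation_base_rate = 0, mutation_elevated_rate = 0,
                     seed = 10)
  expect_equal(nrow(generate_mutations(cfg0, subtypes[1:20])), 0L)
  expect_identical(generate_mutations(cfg, subtypes),
                   generate_mutations(cfg, subtypes))
})

test_that("zero_fraction exercises the expressed-gene filter", {
  cfg <- sim_config(n_genes = 80, n_normal = 30, n_tumor = 10,
                    zero_fraction = 0.6, n_subtypes = 2, n_subtype_genes = 5,
                    seed = 11)
  ref <- generate_reference_expression(cfg)
  frac_zero <- mean(ref$values == 0)
  expect_gt(frac_zero, 0.5)
  expect_lt(frac_zero, 0.7)
})
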