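# Synthetic cohort generator.
#
# Emulates the statistical structure the pipeline assumes: normal samples from
# a latent-factor Gaussian whose pairwise correlation is rho_ref on background
# edges and ~0 elsewhere; tumor samples from the same model except that a
# planted subset of edges is perturbed in a fraction f of tumors; 6-subtype
# mean-shift structure with subtype-specific genes; proportional-hazards
# survival tied to designated genes; subtype-linked mutations.

with_sim_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Parameters of the synthetic cohort. Defaults give a desk-scale cohort with
#' the structure of a tumor/normal expression study: 200 genes, 41 normal and
#' 100 tumor samples, a sparse background network with reference correlation
#' 0.7 on its edges, 20 planted edges perturbed in 95% of tumors with a strong
#' coupling flip, 6 tumor subtypes at a 3-SD mean shift on 10 genes each, and
#' exponential proportional-hazards survival on three designated genes with
#' ~88% censoring.
#'
#' @param n_genes number of genes.
#' @param n_normal number of normal (reference) samples; must be >= 3.
#' @param n_tumor number of tumor samples.
#' @param background_density fraction of all gene pairs used as background
#'   edges. The latent-factor construction needs each gene's summed edge
#'   correlation below 1, so the achievable density at high `rho_ref` is
#'   bounded; the sampler draws as many edges as capacity allows and errors if
#'   an explicit `background_edges` list is infeasible.
#' @param background_edges optional explicit two-column matrix/data.frame of
#'   gene index pairs (or id pairs) overriding `background_density`.
#' @param rho_ref target Pearson correlation on background edges, in (-1, 1).
#' @param n_planted number of planted (perturbed) edges, drawn from the
#'   background; ignored when `planted_edges` given.
#' @param planted_edges optional explicit subset of background edges (same
#'   format as `background_edges`).
#' @param delta perturbation strength: in carrier tumors the planted edge's
#'   latent coupling is replaced by an anti-correlated coupling of amplitude
#'   `delta` (in expression-SD units) whose factor draw is bounded away from
#'   zero, so every carrier sample displaces the edge correlation. `delta = 0`
#'   disables the perturbation entirely (tumors exchangeable with normals).
#' @param planted_frequency fraction f in (0, 1] of tumors carrying each
#'   planted edge's perturbation.
#' @param n_subtypes number of tumor subtypes.
#' @param subtype_effect per-gene mean shift, in SD units, applied to each
#'   subtype's signature genes in that subtype's samples.
#' @param n_subtype_genes signature genes per subtype (disjoint across
#'   subtypes, chosen outside the planted-edge endpoints when possible).
#' @param hazard_genes named numeric vector of log-hazard coefficients per
#'   gene id, or `NULL` to auto-pick three genes with coefficients
#'   `c(1, -1, 0.5)` at simulation time.
#' @param censoring_rate target fraction of censored patients, in [0, 1].
#' @param confound_survival if `TRUE`, pathologic stage is assigned from the
#'   first hazard gene's expression and enters the hazard, creating genuine
#'   confounding for multivariate Cox adjustment to control.
#' @param clinical_missing_rate per-cell missingness applied to race and
#'   microsatellite status (exercises complete-case filtering).
#' @param zero_fraction fraction of expression entries set to zero after
#'   generation (exercises the expressed-gene filter; distorts correlations,
#'   so the default is 0).
#' @param baseline_mean median gene abundance in expression units; per-gene
#'   abundances are log-normal around it with log-scale spread
#'   `baseline_spread`, emulating the orders-of-magnitude abundance
#'   differences of real expression data.
#' @param baseline_spread sdlog of the per-gene abundance distribution.
#' @param baseline_cv per-gene coefficient of variation: a gene's expression
#'   is `mu_g * (1 + baseline_cv * z)` with `z` the latent standard-normal
#'   variable (truncated at 0). Per-gene affine scaling leaves every
#'   gene-gene correlation unchanged.
#' @param mutation_genes gene ids with subtype-elevated mutation rates
#'   (`NULL` = auto-pick four).
#' @param mutation_base_rate,mutation_elevated_rate per-sample Bernoulli
#'   mutation rates outside/inside the designated subtype.
#' @param seed integer seed; every generator is deterministic given the
#'   config.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 200, n_normal = 41, n_tumor = 100,
                       background_density = 0.004, background_edges = NULL,
                       rho_ref = 0.7, n_planted = 20, planted_edges = NULL,
                       delta = 3, planted_frequency = 0.95,
                       n_subtypes = 6, subtype_effect = 3, n_subtype_genes = 10,
                       hazard_genes = NULL, censoring_rate = 0.88,
                       confound_survival = FALSE,
                       clinical_missing_rate = 0.15,
                       zero_fraction = 0, baseline_mean = 100,
                       baseline_spread = 0.8, baseline_cv = 0.04,
                       mutation_genes = NULL, mutation_base_rate = 0.05,
                       mutation_elevated_rate = 0.8, seed = 1L) {
  if (n_normal < 3) ssnet_error("n_normal must be >= 3", "ssnet_config_error")
  if (abs(rho_ref) >= 1) ssnet_error("rho_ref must be in (-1, 1)", "ssnet_config_error")
  if (planted_frequency <= 0 || planted_frequency > 1) {
    ssnet_error("planted_frequency must be in (0, 1]", "ssnet_config_error")
  }
  if (censoring_rate < 0 || censoring_rate > 1) {
    ssnet_error("censoring_rate must be in [0, 1]", "ssnet_config_error")
  }
  if (mutation_base_rate < 0 || mutation_base_rate > 1 ||
      mutation_elevated_rate < 0 || mutation_elevated_rate > 1) {
    ssnet_error("mutation rates must be in [0, 1]", "ssnet_config_error")
  }
  if (zero_fraction < 0 || zero_fraction >= 1) {
    ssnet_error("zero_fraction must be in [0, 1)", "ssnet_config_error")
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

sim_gene_ids <- function(n) sprintf("g%04d", seq_len(n))

normalize_edge_input <- function(x, gene_ids) {
  x <- as.matrix(as.data.frame(x))
  if (ncol(x) < 2) ssnet_error("edge input needs two columns", "ssnet_config_error")
  if (is.numeric(x)) {
    a <- gene_ids[x[, 1]]; b <- gene_ids[x[, 2]]
  } else {
    a <- as.character(x[, 1]); b <- as.character(x[, 2])
  }
  if (anyNA(a) || anyNA(b) || !all(c(a, b) %in% gene_ids)) {
    ssnet_error("edge input refers to unknown genes", "ssnet_config_error")
  }
  unique(edge_key(a, b))
}

# Build the latent-factor model: one shared factor per background edge with
# loading sqrt(|rho|) on each endpoint (sign split for negative rho), plus a
# private noise term scaled so every gene has unit latent variance.
build_sim_model <- function(config) {
  genes <- sim_gene_ids(config$n_genes)
  rho <- config$rho_ref
  cap <- if (abs(rho) > 0) floor(0.95 / abs(rho)) else Inf

  if (!is.null(config$background_edges)) {
    keys <- normalize_edge_input(config$background_edges, genes)
    ends <- split_edge_key(keys)
    deg <- table(c(ends$gene_a, ends$gene_b))
    if (any(deg > cap)) {
      bad <- names(deg)[deg > cap][1]
      ssnet_error(sprintf(
        "infeasible correlation structure: gene %s has degree %d but rho_ref=%.2f allows at most %d shared factors per gene",
        bad, max(deg), rho, cap), "ssnet_generation_error")
    }
  } else {
    target <- round(config$background_density * choose(config$n_genes, 2))
    remaining <- rep(cap, config$n_genes)
    names(remaining) <- genes
    keys <- character(0)
    seen <- new.env(hash = TRUE)
    tries <- 0L
    while (length(keys) < target && tries < 50L * target) {
      pair <- sample.int(config$n_genes, 2)
      k <- edge_key(genes[pair[1]], genes[pair[2]])
      tries <- tries + 1L
      if (!is.null(seen[[k]])) next
      if (remaining[pair[1]] < 1 || remaining[pair[2]] < 1) next
      seen[[k]] <- TRUE
      keys <- c(keys, k)
      remaining[pair] <- remaining[pair] - 1
    }
    if (length(keys) < target) {
      warning(sprintf("background capacity at rho_ref=%.2f allowed only %d of %d requested edges",
                      rho, length(keys), target))
    }
  }
  if (!length(keys)) ssnet_error("no background edges generated", "ssnet_generation_error")
  keys <- sort(keys)
  ends <- split_edge_key(keys)

  planted <- if (!is.null(config$planted_edges)) {
    pk <- normalize_edge_input(config$planted_edges, genes)
    if (!all(pk %in% keys)) {
      ssnet_error("planted_edges must be a subset of background edges", "ssnet_config_error")
    }
    pk
  } else {
    sample(keys, min(config$n_planted, length(keys)))
  }

  l <- sqrt(abs(rho))
  la <- rep(l, length(keys))
  lb <- rep(if (rho < 0) -l else l, length(keys))
  idx_a <- match(ends$gene_a, genes)
  idx_b <- match(ends$gene_b, genes)
  fac_var <- numeric(config$n_genes)
  for (i in seq_along(keys)) {
    fac_var[idx_a[i]] <- fac_var[idx_a[i]] + la[i]^2
    fac_var[idx_b[i]] <- fac_var[idx_b[i]] + lb[i]^2
  }
  if (any(fac_var >= 1)) {
    ssnet_error("infeasible correlation structure: latent factor variance >= 1",
                "ssnet_generation_error")
  }
  # subtype signature genes: disjoint blocks, preferring genes off the network
  edge_genes <- unique(c(ends$gene_a, ends$gene_b))
  # prefer genes untouched by the network, then non-perturbed edge genes;
  # planted-edge endpoints last (their carrier-inflated variance would
  # otherwise contaminate the subtype mean-shift signal)
  shuffle <- function(x) x[sample.int(length(x))]
  planted_ends <- unique(unlist(split_edge_key(planted)))
  pool <- c(shuffle(setdiff(genes, edge_genes)),
            shuffle(setdiff(edge_genes, planted_ends)),
            shuffle(planted_ends))
  need <- config$n_subtypes * config$n_subtype_genes
  if (need > length(genes)) {
    ssnet_error("n_subtypes * n_subtype_genes exceeds gene count", "ssnet_config_error")
  }
  sub_genes <- split(pool[seq_len(need)],
                     rep(seq_len(config$n_subtypes), each = config$n_subtype_genes))

  mu <- exp(stats::rnorm(config$n_genes, log(config$baseline_mean),
                         config$baseline_spread))
  names(mu) <- genes
  list(genes = genes, edge_keys = keys, idx_a = idx_a, idx_b = idx_b,
       loading_a = la, loading_b = lb, noise_sd = sqrt(1 - fac_var),
       mu = mu, planted = sort(planted), subtype_genes = sub_genes,
       config = config)
}

draw_latent <- function(model, m) {
  ne <- length(model$edge_keys)
  f <- matrix(stats::rnorm(ne * m), ne, m)
  z <- model$noise_sd * matrix(stats::rnorm(model$config$n_genes * m),
                               model$config$n_genes, m)
  for (i in seq_len(ne)) {
    z[model$idx_a[i], ] <- z[model$idx_a[i], ] + model$loading_a[i] * f[i, ]
    z[model$idx_b[i], ] <- z[model$idx_b[i], ] + model$loading_b[i] * f[i, ]
  }
  list(z = z, f = f)
}

to_expression_units <- function(z, model) {
  config <- model$config
  x <- model$mu * (1 + config$baseline_cv * z)
  x[x < 0] <- 0
  if (config$zero_fraction > 0) {
    drop <- stats::runif(length(x)) < config$zero_fraction
    x[drop] <- 0
  }
  x
}

#' Generate reference (normal) expression
#'
#' Draws `n_normal` samples from the latent-factor Gaussian model: pairwise
#' correlation `rho_ref` on background edges, ~0 off-network, then shifts and
#' scales to nonnegative expression units. The fitted model is attached as
#' attribute `"sim_model"` for [generate_tumor_samples()].
#'
#' @param config a [sim_config()].
#' @return An [expression_matrix()] of normal samples, with attribute
#'   `sim_model`.
#' @export
generate_reference_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config$seed, {
    model <- build_sim_model(config)
    lat <- draw_latent(model, config$n_normal)
    x <- to_expression_units(lat$z, model)
    rownames(x) <- model$genes
    colnames(x) <- sprintf("N%03d", seq_len(config$n_normal))
    expr <- expression_matrix(x, rep("normal", config$n_normal))
    attr(expr, "sim_model") <- model
    expr
  })
}

#' Generate tumor samples with planted perturbations and subtype structure
#'
#' Each tumor is drawn from the reference model; for each planted edge a
#' fraction `planted_frequency` of tumors (carriers) have the edge's latent
#' coupling replaced by an anti-correlated coupling of amplitude `delta` with
#' a factor draw bounded away from zero (`|F| >= 1`), displacing the edge's
#' correlation in every carrier. Tumors are assigned to `n_subtypes` subtypes
#' of near-equal size and each subtype's signature genes are mean-shifted by
#' `subtype_effect` SD in its samples.
#'
#' @param config a [sim_config()].
#' @param reference_model the attribute attached by
#'   [generate_reference_expression()], or the reference expression matrix
#'   itself.
#' @return An [expression_matrix()] of tumor samples with attributes
#'   `subtypes` (named vector sample -> subtype), `carriers` (list per planted
#'   edge key of carrier sample ids), and `sim_model`.
#' @export
generate_tumor_samples <- function(config, reference_model) {
  stopifnot(inherits(config, "sim_config"))
  model <- if (inherits(reference_model, "expression_matrix")) {
    attr(reference_model, "sim_model")
  } else reference_model
  if (is.null(model)) ssnet_error("reference model required", "ssnet_config_error")
  with_sim_seed(config$seed + 1L, {
    m <- config$n_tumor
    lat <- draw_latent(model, m)
    z <- lat$z
    n_carrier <- round(config$planted_frequency * m)
    if (n_carrier < 1 && config$delta > 0) {
      warning("planted_frequency * n_tumor < 1: no tumor carries the perturbation")
    }
    carriers <- stats::setNames(vector("list", length(model$planted)), model$planted)
    ids <- sprintf("T%03d", seq_len(m))
    if (config$delta > 0 && n_carrier >= 1) {
      for (k in model$planted) {
        e <- match(k, model$edge_keys)
        who <- sort(sample.int(m, n_carrier))
        carriers[[k]] <- ids[who]
        g <- sample(c(-1, 1), length(who), replace = TRUE) *
          (1 + abs(stats::rnorm(length(who))))
        ia <- model$idx_a[e]; ib <- model$idx_b[e]
        z[ia, who] <- z[ia, who] - model$loading_a[e] * lat$f[e, who] + config$delta * g
        z[ib, who] <- z[ib, who] - model$loading_b[e] * lat$f[e, who] - config$delta * g
      }
    }
    subtypes <- stats::setNames(
      sample(rep_len(seq_len(config$n_subtypes), m)), ids)
    if (config$subtype_effect != 0) {
      for (s in seq_len(config$n_subtypes)) {
        gi <- match(model$subtype_genes[[s]], model$genes)
        z[gi, subtypes == s] <- z[gi, subtypes == s] + config$subtype_effect
      }
    }
    x <- to_expression_units(z, model)
    rownames(x) <- model$genes
    colnames(x) <- ids
    expr <- expression_matrix(x, rep("tumor", m))
    attr(expr, "subtypes") <- subtypes
    attr(expr, "carriers") <- carriers
    attr(expr, "sim_model") <- model
    expr
  })
}

#' Generate a survival/clinical table for the tumor samples
#'
#' Event times follow an exponential proportional-hazards model with
#' log-hazard `sum(beta_g * standardized expression of g)` over the hazard
#' genes; censoring is independent exponential tuned to the target censoring
#' fraction. Confounder columns are filled with categorical draws, by default
#' independent of survival; with `confound_survival = TRUE`, pathologic stage
#' is derived from the first hazard gene's expression and enters the hazard.
#'
#' @param config a [sim_config()].
#' @param tumor_expr tumor [expression_matrix()] from
#'   [generate_tumor_samples()].
#' @return A [clinical_table] with attribute `hazard_genes` (the named beta
#'   vector used).
#' @export
generate_survival <- function(config, tumor_expr) {
  stopifnot(inherits(config, "sim_config"), inherits(tumor_expr, "expression_matrix"))
  with_sim_seed(config$seed + 2L, {
    ids <- tumor_expr$sample_ids
    m <- length(ids)
    beta <- config$hazard_genes
    if (is.null(beta)) {
      pool <- setdiff(tumor_expr$gene_ids,
                      unlist(attr(tumor_expr, "sim_model")$subtype_genes))
      picked <- sample(pool, 3)
      beta <- stats::setNames(c(1, -1, 0.5), picked)
    }
    if (!all(names(beta) %in% tumor_expr$gene_ids)) {
      ssnet_error("hazard genes absent from tumor expression", "ssnet_config_error")
    }
    if (all(beta == 0) && config$censoring_rate >= 1) {
      ssnet_error("degenerate survival data: all beta zero and full censoring",
                  "ssnet_generation_error")
    }
    xs <- tumor_expr$values[names(beta), , drop = FALSE]
    zs <- t(scale(t(xs)))
    zs[is.nan(zs)] <- 0
    lp <- drop(crossprod(zs, beta))

    stage_levels <- c("stage i", "stage ii", "stage iii", "stage iv")
    if (config$confound_survival) {
      g1 <- zs[1, ] + stats::rnorm(m, sd = 0.5)
      stage <- stage_levels[pmin(4, pmax(1, findInterval(g1, c(-0.7, 0.3, 1.1)) + 1))]
      lp <- lp + 0.5 * (match(stage, stage_levels) - 1)
    } else {
      stage <- sample(stage_levels, m, replace = TRUE, prob = c(0.2, 0.4, 0.25, 0.15))
    }

    lambda0 <- log(2) / 730  # baseline median ~2 years, in days
    rate <- lambda0 * exp(lp)
    t_event <- stats::rexp(m, rate)
    cr <- min(config$censoring_rate, 0.999)
    if (cr > 0) {
      mu <- mean(rate) * cr / (1 - cr)
      t_cens <- stats::rexp(m, mu)
    } else {
      t_cens <- rep(Inf, m)
    }
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    maybe_na <- function(x) {
      x[stats::runif(m) < config$clinical_missing_rate] <- NA
      x
    }
    df <- data.frame(
      patient_id = ids,
      survival_time = round(time, 1),
      event = event,
      sex = sample(c("male", "female"), m, replace = TRUE),
      pathologic_stage = stage,
      retrospective = sample(c("yes", "no"), m, replace = TRUE, prob = c(0.6, 0.4)),
      race = maybe_na(sample(c("white", "black", "asian"), m, replace = TRUE,
                             prob = c(0.7, 0.2, 0.1))),
      year_of_diagnosis = sample(2000:2013, m, replace = TRUE),
      age_at_diagnosis = pmin(90, pmax(30, round(stats::rnorm(m, 67, 12)))),
      microsatellite_status = maybe_na(sample(c("mss", "msi-l", "msi-h"), m,
                                              replace = TRUE, prob = c(0.7, 0.15, 0.15))),
      stringsAsFactors = FALSE
    )
    out <- validate_clinical(df)
    attr(out, "hazard_genes") <- beta
    out
  })
}

#' Generate gene sets with controlled overlap against a query
#'
#' Builds a collection whose overlaps with `planted_genes` are known by
#' construction, so hypergeometric p-values are predictable: one set equal to
#' the planted genes, sets with prescribed overlap `k`, and a random set.
#'
#' @param config a [sim_config()].
#' @param planted_genes the query gene set the overlaps are controlled
#'   against.
#' @param set_sizes,overlaps equal-length integer vectors: each produced set
#'   has `set_sizes[i]` genes of which `overlaps[i]` come from
#'   `planted_genes`.
#' @return A [gene_set_collection()] with `universe_size = n_genes`.
#' @export
generate_gene_sets <- function(config, planted_genes,
                               set_sizes = c(40, 25, 15),
                               overlaps = c(10, 5, 0)) {
  stopifnot(inherits(config, "sim_config"), length(set_sizes) == length(overlaps))
  universe <- sim_gene_ids(config$n_genes)
  planted_genes <- unique(as.character(planted_genes))
  if (!all(planted_genes %in% universe)) {
    ssnet_error("planted genes outside the gene universe", "ssnet_config_error")
  }
  if (any(overlaps > set_sizes)) {
    ssnet_error("requested overlap exceeds set size", "ssnet_config_error")
  }
  if (any(overlaps > length(planted_genes))) {
    ssnet_error("requested overlap exceeds planted gene count", "ssnet_config_error")
  }
  with_sim_seed(config$seed + 3L, {
    outside <- setdiff(universe, planted_genes)
    sets <- list(planted_exact = planted_genes)
    for (i in seq_along(set_sizes)) {
      nm <- sprintf("overlap_k%d_A%d", overlaps[i], set_sizes[i])
      sets[[nm]] <- c(if (overlaps[i] > 0) sample(planted_genes, overlaps[i]),
                      sample(outside, set_sizes[i] - overlaps[i]))
    }
    sets$random <- sample(universe, min(30, config$n_genes))
    gene_set_collection(sets, universe_size = config$n_genes)
  })
}

#' Generate a mutation table with subtype-elevated genes
#'
#' Per-gene Bernoulli mutation per tumor sample: the designated mutation
#' genes mutate at `mutation_elevated_rate` in subtype 1 samples and at
#' `mutation_base_rate` elsewhere; ten background genes mutate at the base
#' rate in all samples.
#'
#' @param config a [sim_config()].
#' @param subtypes named vector sample id -> subtype (attribute of
#'   [generate_tumor_samples()]).
#' @return A `mutation_table` data.frame with attribute `elevated_genes`.
#' @export
generate_mutations <- function(config, subtypes) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config$seed + 4L, {
    universe <- sim_gene_ids(config$n_genes)
    elev <- config$mutation_genes
    if (is.null(elev)) elev <- sample(universe, 4)
    background <- sample(setdiff(universe, elev), min(10, config$n_genes - length(elev)))
    ids <- names(subtypes)
    rows <- list()
    classes <- c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del", "Silent")
    for (g in c(elev, background)) {
      rate <- ifelse(g %in% elev & subtypes == 1,
                     config$mutation_elevated_rate, config$mutation_base_rate)
      hit <- stats::runif(length(ids)) < rate
      if (any(hit)) {
        rows[[g]] <- data.frame(
          sample_id = ids[hit], gene_id = g,
          variant_classification = sample(classes, sum(hit), replace = TRUE,
                                          prob = c(0.6, 0.15, 0.1, 0.15)),
          variant_type = sample(c("SNP", "DEL", "INS"), sum(hit), replace = TRUE,
                                prob = c(0.8, 0.12, 0.08)),
          stringsAsFactors = FALSE)
      }
    }
    out <- if (length(rows)) do.call(rbind, rows) else {
      data.frame(sample_id = character(0), gene_id = character(0),
                 variant_classification = character(0),
                 variant_type = character(0), stringsAsFactors = FALSE)
    }
    rownames(out) <- NULL
    class(out) <- c("mutation_table", "data.frame")
    attr(out, "elevated_genes") <- elev
    out
  })
}

#' Simulate a complete cohort
#'
#' Runs all generators in order and returns every object the pipeline needs,
#' plus the ground truth for recovery checks.
#'
#' @param config a [sim_config()].
#' @return A list with `expr` (combined normal+tumor [expression_matrix()]),
#'   `reference`, `tumor`, `background` ([scored_edge_list()] over the
#'   background edges), `clinical`, `gene_sets`, `mutations`, and `truth`
#'   (list: `planted_edges`, `carriers`, `subtypes`, `subtype_genes`,
#'   `hazard_genes`, `elevated_mutation_genes`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  reference <- generate_reference_expression(config)
  model <- attr(reference, "sim_model")
  tumor <- generate_tumor_samples(config, reference)
  clinical <- generate_survival(config, tumor)
  planted_genes <- unique(unlist(split_edge_key(model$planted)))
  gene_sets <- generate_gene_sets(config, planted_genes)
  subtypes <- attr(tumor, "subtypes")
  mutations <- generate_mutations(config, subtypes)
  ends <- split_edge_key(model$edge_keys)
  background <- scored_edge_list(ends$gene_a, ends$gene_b,
                                 rep(900L, length(model$edge_keys)))
  vals <- cbind(reference$values, tumor$values)
  expr <- expression_matrix(vals, c(reference$sample_class, tumor$sample_class))
  list(expr = expr, reference = reference, tumor = tumor,
       background = background, clinical = clinical,
       gene_sets = gene_sets, mutations = mutations,
       truth = list(planted_edges = model$planted,
                    carriers = attr(tumor, "carriers"),
                    subtypes = subtypes,
                    subtype_genes = model$subtype_genes,
                    hazard_genes = attr(clinical, "hazard_genes"),
                    elevated_mutation_genes = attr(mutations, "elevated_genes")))
}
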