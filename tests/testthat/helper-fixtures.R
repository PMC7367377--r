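# Shared fixtures and small oracles, all built in code at test time.

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# 3-gene x 4-sample expression TSV with known values
tiny_expression_file <- function() {
  write_lines_tmp(c(
    "gene\ts1\ts2\ts3\ts4",
    "gA\t1.5\t2.5\t0\t4.25",
    "gB\t3\t0\t0\t1",
    "gC\t10\t11\t12\t13"))
}

tiny_class_map <- c(s1 = "tumor", s2 = "tumor", s3 = "normal", s4 = "normal")

# 10-line scored edge file; exactly 4 edges score strictly above 300
# (b-c appears twice reversed and collapses to one edge, max score kept)
tiny_edge_file <- function() {
  write_lines_tmp(c(
    "protein1\tprotein2\tscore",
    "a\tb\t300",    # boundary: dropped
    "a\tc\t301",    # kept
    "b\tc\t500",    # kept (max of 500/400)
    "c\tb\t400",
    "d\td\t900",    # self loop: dropped
    "d\te\t299",
    "e\tf\t800",    # kept
    "f\tg\t150",
    "g\th\t301",    # kept
    "h\ta\t100"))
}

tiny_gmt_file <- function() {
  write_lines_tmp(c(
    "setA\tdesc\tg1\tg2\tg3",
    "setB\tna\tg2\tg4"), ext = ".gmt")
}

# 5 patients, 2 with missing race; complete cases on all confounders = p1, p4
tiny_clinical_file <- function() {
  write_lines_tmp(c(
    paste("patient_id", "survival_time", "event", "sex", "pathologic_stage",
          "retrospective", "race", "year_of_diagnosis", "age_at_diagnosis",
          "microsatellite_status", sep = "\t"),
    "p1\t100\t1\tmale\tstage i\tyes\twhite\t2005\t60\tmss",
    "p2\t250\t0\tfemale\tstage ii\tno\t\t2006\t65\tmsi-h",
    "p3\t300\t1\tmale\tstage iii\tyes\t\t2007\t70\tmss",
    "p4\t50\t0\tfemale\tstage iv\tno\tasian\t2008\t55\tmsi-l",
    "p5\t400\t1\tmale\tstage ii\tyes\twhite\t2009\t80\t"))
}

tiny_mutation_file <- function() {
  write_lines_tmp(c(
    "Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification\tVariant_Type",
    "X\tT1\tMissense_Mutation\tSNP",
    "X\tT2\tNonsense_Mutation\tSNP",
    "X\tT2\tMissense_Mutation\tDEL",
    "Y\tT3\tSilent\tSNP"))
}

# deterministic expression matrix fixture
random_expression <- function(n_genes, n_samples, seed = 1,
                              class = rep("normal", n_samples)) {
  set.seed(seed)
  vals <- matrix(abs(rnorm(n_genes * n_samples, 10, 3)), n_genes, n_samples,
                 dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                 sprintf("s%02d", seq_len(n_samples))))
  expression_matrix(vals, class)
}

# minimal ssn stub for set-level operations
ssn_stub <- function(sample_id, pairs) {
  edges <- if (length(pairs)) {
    do.call(rbind, lapply(pairs, function(p) {
      data.frame(gene_a = min(p), gene_b = max(p), pcc_ref = 0.5,
                 pcc_perturbed = 0.6, delta_pcc = 0.1, z = 3, p = 0.001,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(gene_a = character(0), gene_b = character(0),
               pcc_ref = numeric(0), pcc_perturbed = numeric(0),
               delta_pcc = numeric(0), z = numeric(0), p = numeric(0))
  }
  structure(list(sample_id = sample_id, alpha = 0.05,
                 n_tested = max(10L, nrow(edges)), edges = edges),
            class = "ssn")
}

# adjusted Rand index (independent of any clustering code under test)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  s <- sum(choose(tab, 2))
  ra <- sum(choose(rowSums(tab), 2))
  rb <- sum(choose(colSums(tab), 2))
  expected <- ra * rb / choose(length(a), 2)
  (s - expected) / ((ra + rb) / 2 - expected)
}

# enumeration oracle for the hypergeometric upper tail, plain choose() sums;
# sums P(X = i) upward from k (identical to 1 - sum_{i<k}, but exact for
# tiny tails)
hyper_tail_enum <- function(N, A, n, k) {
  if (k == 0) return(1)
  i <- k:min(A, n)
  sum(choose(A, i) * choose(N - A, n - i)) / choose(N, n)
}
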