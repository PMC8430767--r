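# Structural design matrices, the bootstrapped elastic-net protocol, and
# per-chromosome DEG pinpointing.

test_that("design matrix column counts follow the model definitions", {
  ann <- small_sim_annotation()
  pair <- sim_background_pair(ann, simulation_spec(n_genes = 1500, seed = 2))
  f <- annotate_features(pair$a, ann)
  d_len <- build_design("chrom_length", pair$a, annotation = ann)
  expect_equal(ncol(d_len$X), nrow(ann$chromosomes))
  expect_true(all(rowSums(d_len$X) == 1))
  d_ends <- build_design("chrom_ends", pair$a, f)
  expect_equal(ncol(d_ends$X), 3L)
  expect_true(all(rowSums(d_ends$X) == 1))
  expect_equal(ncol(build_design("alu", pair$a, f)$X), 1L)
  expect_equal(ncol(build_design("replication", pair$a, f)$X), 1L)
  d_tad <- build_design("tads", pair$a, f)
  expect_true("no_TAD" %in% colnames(d_tad$X))
  d_lad <- build_design("lads", pair$a, f)
  expect_true("no_LAD" %in% colnames(d_lad$X))
  d_cyto <- build_design("cytobands", pair$a, f)
  expect_false(any(grepl("^no_", colnames(d_cyto$X))))
  # each occupied-domain model has one column per occupied domain (+ outside)
  expect_equal(ncol(d_tad$X),
               length(unique(stats::na.omit(f$tad_id))) + 1L)
  expect_error(build_design("nope", pair$a, f), "unknown model_id")
  expect_error(build_design("alu", pair$a, NULL), "feature error")
})

test_that("degree-2 expansion counts match brute-force monomial enumeration", {
  # independent oracle: enumerate multisets of size <= 2 over p variables
  enumerate_monomials <- function(p) {
    singles <- p
    pairs_with_rep <- nrow(unique(t(apply(
      expand.grid(seq_len(p), seq_len(p)), 1, sort))))
    1L + singles + pairs_with_rep
  }
  for (p in c(2, 3, 5, 8, 13, 27, 29, 30)) {
    X <- matrix(stats::rnorm(10 * p), 10, p,
                dimnames = list(NULL, paste0("v", seq_len(p))))
    expect_equal(ncol(grcr:::poly2_expand(X)), enumerate_monomials(p))
    expect_equal(ncol(grcr:::poly2_expand(X)), choose(p + 2, 2))
  }
})

test_that("a noiseless linear response is fitted perfectly at tiny penalty", {
  set.seed(5)
  X <- matrix(stats::rnorm(4000), 200, 20,
              dimnames = list(NULL, paste0("v", 1:20)))
  beta <- stats::rnorm(20)
  design <- structure(list(model_id = "chrom_length", X = X,
                           y = as.numeric(X %*% beta),
                           gene_id = sprintf("g%03d", 1:200),
                           column_names = colnames(X), n_dropped = 0L),
                      class = "grcr_design")
  fit <- fit_bootstrap(design, reps = 30, seed = 1, lambda = 1e-8)
  expect_gte(fit$mean_r2, 0.99)
})

test_that("held-out evaluation has no optimistic bias on pure noise", {
  ann <- small_sim_annotation()
  pair <- sim_background_pair(ann, simulation_spec(n_genes = 10000, seed = 3))
  d <- build_design("chrom_length", pair$a, annotation = ann)
  fit <- fit_bootstrap(d, reps = 200, seed = 2)
  expect_lte(fit$mean_r2, 0.02)
})

test_that("the fit is invariant to row order through gene-id keyed splits", {
  set.seed(6)
  X <- matrix(stats::rnorm(2000), 100, 20,
              dimnames = list(NULL, paste0("v", 1:20)))
  y <- stats::rnorm(100)
  ids <- sprintf("g%03d", sample(1:100))
  mk <- function(ord) structure(list(model_id = "chrom_length",
                                     X = X[ord, ], y = y[ord],
                                     gene_id = ids[ord],
                                     column_names = colnames(X),
                                     n_dropped = 0L),
                                class = "grcr_design")
  f1 <- fit_bootstrap(mk(1:100), reps = 25, seed = 9)
  f2 <- fit_bootstrap(mk(sample(1:100)), reps = 25, seed = 9)
  expect_equal(f1$mean_r2, f2$mean_r2, tolerance = 1e-12)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-12)
})

test_that("constant responses are flagged instead of fitted", {
  design <- structure(list(model_id = "alu",
                           X = matrix(stats::rnorm(50), 50, 1,
                                      dimnames = list(NULL, "alu_count")),
                           y = rep(0.3, 50), gene_id = sprintf("g%02d", 1:50),
                           column_names = "alu_count", n_dropped = 0L),
                      class = "grcr_design")
  fit <- fit_bootstrap(design, reps = 5, seed = 1)
  expect_true(is.na(fit$mean_r2))
  expect_equal(fit$reason, "constant response")
})

test_that("chromosome coefficients recover planted per-chromosome shifts", {
  ann <- small_sim_annotation()
  pair <- sim_background_pair(ann, simulation_spec(n_genes = 5000, seed = 8))
  tab <- pair$a
  up <- tab$genes$chromosome == "chrA"
  dn <- tab$genes$chromosome == "chrC"
  tab$genes$logfc[up] <- tab$genes$logfc[up] + 0.5
  tab$genes$logfc[dn] <- tab$genes$logfc[dn] - 0.5
  fit <- fit_bootstrap(build_design("chrom_length", tab, annotation = ann),
                       reps = 60, seed = 4)
  cc <- chromosome_coefficients(fit)
  expect_equal(nrow(cc), nrow(ann$chromosomes))
  expect_gt(cc$coefficient[cc$chromosome == "chrA"], 0)
  expect_lt(cc$coefficient[cc$chromosome == "chrC"], 0)
  expect_error(chromosome_coefficients(
    fit_bootstrap(build_design("chrom_ends", tab,
                               annotate_features(tab, ann)),
                  reps = 5, seed = 1)), "chrom_length")
})

test_that("pinpointing reports per-chromosome DEG percentages", {
  g <- data.frame(
    gene_id = sprintf("g%03d", 1:100), chromosome = "chr1",
    start_bp = seq(1e4, 1e6, length.out = 100),
    logfc = c(rep(1, 7), rep(-1, 3), rep(0.1, 90)),
    avg_expr = 1,
    p_value = c(rep(0.01, 10), rep(0.5, 90)))
  tab <- comparison_table(g)
  pp <- pinpoint_deg(tab)
  expect_equal(pp$pct_deg, 10)
  expect_equal(pp$pct_up, 7)
  expect_equal(pp$pct_down, 3)
  expect_equal(pp$pct_up + pp$pct_down, pp$pct_deg)
  # the threshold is strict: p exactly at alpha is not significant
  g$p_value <- rep(0.05, 100)
  expect_equal(pinpoint_deg(comparison_table(g))$pct_deg, 0)
  # logFC exactly 0 counts neither up, down, nor in the total
  g$p_value <- rep(0.01, 100); g$logfc <- rep(0, 100)
  pp0 <- pinpoint_deg(comparison_table(g))
  expect_equal(pp0$pct_deg, 0)
  # uniform-null p-values land near the binomial expectation
  set.seed(11)
  gu <- data.frame(gene_id = sprintf("u%05d", 1:10000), chromosome = "chr1",
                   start_bp = seq_len(10000) * 100,
                   logfc = stats::rnorm(10000), avg_expr = 1,
                   p_value = stats::runif(10000))
  ppu <- pinpoint_deg(comparison_table(gu))
  expect_gt(ppu$pct_deg, 4)
  expect_lt(ppu$pct_deg, 6)
})
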