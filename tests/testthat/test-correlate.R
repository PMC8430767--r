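# Correlation, permutation null, sigma score, region bin set.

trace_from <- function(tab, ann, ...) bin_trace(tab, ann, min_genes = 1, ...)

test_that("spearman_correlate matches a definitional rank oracle", {
  ann <- genome_annotation(data.frame(name = "chr1", length_bp = 2e8,
                                      centromere_bp = 1e8))
  set.seed(3)
  pos <- seq(1e6, 96e6, by = 5e6)   # one gene per window step
  n <- length(pos)
  ids <- sprintf("g%02d", 1:n)
  va <- stats::rnorm(n); vb <- stats::rnorm(n)
  ta <- trace_from(make_table(ids, "chr1", pos, va, annotation = ann), ann)
  tb <- trace_from(make_table(ids, "chr1", pos, vb, annotation = ann), ann)
  res <- spearman_correlate(ta, tb)
  # independent oracle: manual ranks, manual Pearson sum formula
  manual_rank <- function(x) {
    r <- numeric(length(x))
    for (i in seq_along(x))
      r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
    r
  }
  pearson <- function(x, y) {
    xm <- x - mean(x); ym <- y - mean(y)
    sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  }
  shared <- intersect(ta$keys, tb$keys)
  oracle <- pearson(manual_rank(ta$bins$value[match(shared, ta$keys)]),
                    manual_rank(tb$bins$value[match(shared, tb$keys)]))
  expect_equal(res$rho, oracle, tolerance = 1e-12)
  expect_equal(res$n_shared_bins, length(shared))
  # identical traces give 1, rank-reversed traces give -1
  expect_equal(spearman_correlate(ta, ta)$rho, 1)
  tneg <- ta
  tneg$bins$value <- -tneg$bins$value
  expect_equal(spearman_correlate(ta, tneg)$rho, -1)
  # rho is invariant under strictly monotone transforms of either trace
  tmono <- ta
  tmono$bins$value <- exp(3 * tmono$bins$value) - 5
  expect_equal(spearman_correlate(tmono, tb)$rho, res$rho)
})

test_that("too few shared bins yields an undefined record with a reason", {
  ann <- genome_annotation(data.frame(name = "chr1", length_bp = 4e7,
                                      centromere_bp = 2e7))
  ta <- trace_from(make_table(c("g1", "g2"), "chr1", c(1e6, 2e6), c(1, 2),
                              annotation = ann), ann)
  tb <- trace_from(make_table(c("g1", "g2"), "chr1", c(1e6, 2e6), c(2, 1),
                              annotation = ann), ann)
  res <- spearman_correlate(ta, tb)
  expect_true(is.na(res$rho))
  expect_match(res$reason, "shared bins")
})

test_that("shuffling an identical pair keeps rho at 1 with zero spread", {
  ann <- small_sim_annotation()
  pair <- sim_background_pair(ann, simulation_spec(n_genes = 2000, seed = 5))
  nul <- shuffle_null(pair$a, pair$a, ann, reps = 20, seed = 9,
                      top_n = 500, min_genes = 5)
  expect_equal(nul$rho_mean, 1)
  expect_equal(nul$rho_sd, 0)
})

test_that("the fast permutation path equals the naive shuffled pipeline", {
  ann <- small_sim_annotation()
  spec <- simulation_spec(n_genes = 3000, n_sites = 10, seed = 8)
  pair <- plant_grcr_sites(sim_background_pair(ann, spec), ann, spec)$tables
  seed <- 123
  fast <- shuffle_null(pair$a, pair$b, ann, reps = 1, seed = seed,
                       top_n = 700, min_genes = 5)
  # naive route: draw the same permutation, rewrite the location columns of
  # both tables, then run the public pipeline
  u <- union(pair$a$genes$gene_id, pair$b$genes$gene_id)
  perm <- grcr:::with_seed(seed, sample.int(length(u)))
  reloc <- function(tab) {
    i <- match(tab$genes$gene_id, u)
    src <- match(u[perm[i]], pair$a$genes$gene_id)
    tab$genes$chromosome <- pair$a$genes$chromosome[src]
    tab$genes$start_bp <- pair$a$genes$start_bp[src]
    comparison_table(tab$genes, label = tab$label, annotation = ann)
  }
  ta <- bin_trace(select_top_n(reloc(pair$a), 700), ann, min_genes = 5)
  tb <- bin_trace(select_top_n(reloc(pair$b), 700), ann, min_genes = 5)
  naive_rho <- spearman_correlate(ta, tb)$rho
  expect_equal(fast$rho_samples[1], naive_rho, tolerance = 1e-12)
})

test_that("grcr_score reproduces the sigma/tail relationship", {
  fake_cor <- structure(list(rho = 0.8, label_a = "a", label_b = "b"),
                        class = "grcr_cor")
  fake_null <- structure(list(reps = 1000L, rho_mean = 0.5, rho_sd = 0.1,
                              rho_samples = NULL, seed = 1),
                         class = "grcr_null")
  sc <- grcr_score(fake_cor, fake_null)
  expect_equal(sc$diff, 0.3)
  expect_equal(sc$z_sigma, 3)
  expect_equal(100 * sc$tail_prob, 0.27, tolerance = 0.001)
  # no difference: sigma 0, tail probability 1
  fake_null$rho_mean <- 0.8
  sc0 <- grcr_score(fake_cor, fake_null)
  expect_equal(sc0$z_sigma, 0)
  expect_equal(sc0$tail_prob, 1)
  # zero spread with a non-zero difference flags an infinite sigma
  fake_null$rho_mean <- 0.5; fake_null$rho_sd <- 0
  sci <- grcr_score(fake_cor, fake_null)
  expect_true(is.infinite(sci$z_sigma))
  expect_true(sci$degenerate)
  # stored-draw empirical p agrees with the normal tail for a normal null
  set.seed(4)
  draws <- stats::rnorm(20000, 0.5, 0.1)
  fake_null$rho_sd <- 0.1; fake_null$rho_samples <- draws
  fake_null$reps <- length(draws)
  fake_cor$rho <- 0.65
  sce <- grcr_score(fake_cor, fake_null)
  expect_lt(abs(sce$empirical_p - stats::pnorm(0.65, 0.5, 0.1,
                                               lower.tail = FALSE)), 0.005)
})

test_that("the run-level BH pass fills adjusted p-values over the family", {
  mk_cor <- function(p) structure(list(rho = 0.5, p_value = p,
                                       adj_p = NA_real_),
                                  class = "grcr_cor")
  cors <- lapply(c(0.001, 0.01, 0.02, 0.5, NA), mk_cor)
  out <- adjust_correlations(cors)
  adj <- vapply(out, function(x) x$adj_p, numeric(1))
  expect_equal(adj[1:4], bh_stepup(c(0.001, 0.01, 0.02, 0.5)),
               tolerance = 1e-12)
  expect_true(all(adj[1:4] >= c(0.001, 0.01, 0.02, 0.5)))
  expect_true(is.na(adj[5]))
})

test_that("shared gene fraction is the Jaccard fraction of contributors", {
  mk <- function(ids) list(contributors = list(ids))
  expect_equal(shared_gene_fraction(mk(c("a", "b")), mk(c("a", "b"))), 1)
  expect_equal(shared_gene_fraction(mk(c("a", "b")), mk(c("c", "d"))), 0)
  expect_equal(shared_gene_fraction(mk(c("a", "b", "c")),
                                    mk(c("b", "c", "d"))), 0.5)
  out <- shared_gene_fraction(mk(character(0)), mk(character(0)))
  expect_true(is.na(out))
})

test_that("region bins are merged shared windows projected onto 1 Mb tiles", {
  ann <- genome_annotation(data.frame(name = "chr1", length_bp = 6e7,
                                      centromere_bp = 3e7))
  tab_a <- make_table(paste0("a", 1:4), "chr1", c(1e6, 2e6, 6e6, 21e6),
                      c(1, 2, 3, 4), annotation = ann)
  tab_b <- make_table(paste0("b", 1:4), "chr1", c(1.5e6, 7e6, 31e6, 41e6),
                      c(1, 2, 3, 4), annotation = ann)
  ta <- trace_from(tab_a, ann)
  tb <- trace_from(tab_b, ann)
  # windows starting at 0 and 5 Mb are retained in both -> merged [0, 15 Mb)
  bins <- grcr_bin_set(ta, tb)
  expect_equal(nrow(bins), 15L)
  expect_equal(sort(bins$bin_start), (0:14) * 1e6)
  # a single shared 10 Mb window projects onto exactly 10 bins
  one_a <- trace_from(make_table("x", "chr1", 21e6, 1, annotation = ann), ann)
  one_b <- trace_from(make_table("y", "chr1", 29e6, 1, annotation = ann), ann)
  shared_one <- grcr_bin_set(one_a, one_b)
  expect_equal(nrow(shared_one), 10L)
  expect_equal(range(shared_one$bin_start), c(20e6, 29e6))
  # disjoint retained windows give an empty set
  far_b <- trace_from(make_table("z", "chr1", 51e6, 1, annotation = ann), ann)
  expect_equal(nrow(grcr_bin_set(one_a, far_b)), 0L)
})

test_that("permutation null is exchangeable on an already-shuffled pair", {
  ann <- small_sim_annotation()
  spec <- simulation_spec(n_genes = 3000, n_sites = 20, seed = 10)
  pair <- plant_grcr_sites(sim_background_pair(ann, spec), ann, spec)$tables
  n1 <- shuffle_null(pair$a, pair$b, ann, reps = 500, seed = 1,
                     top_n = 700, min_genes = 5)
  # pre-shuffle the pair once, then apply the null again
  u <- union(pair$a$genes$gene_id, pair$b$genes$gene_id)
  perm <- grcr:::with_seed(77, sample.int(length(u)))
  reloc <- function(tab) {
    i <- match(tab$genes$gene_id, u)
    src <- match(u[perm[i]], pair$a$genes$gene_id)
    tab$genes$chromosome <- pair$a$genes$chromosome[src]
    tab$genes$start_bp <- pair$a$genes$start_bp[src]
    comparison_table(tab$genes, label = tab$label, annotation = ann)
  }
  n2 <- shuffle_null(reloc(pair$a), reloc(pair$b), ann, reps = 500, seed = 2,
                     top_n = 700, min_genes = 5)
  # rank-based coefficients over few bins can tie across repetitions, so
  # the KS p-value is approximate; that is ample for this invariant
  ks <- suppressWarnings(stats::ks.test(n1$rho_samples, n2$rho_samples))
  expect_gt(ks$p.value, 0.01)
})

test_that("background-only pairs keep the sigma score under control", {
  ann <- small_sim_annotation()
  zs <- vapply(1:12, function(s) {
    pair <- sim_background_pair(ann, simulation_spec(n_genes = 3000,
                                                     seed = 400 + s))
    fit <- grcr_compare(pair$a, pair$b, ann, top_n = 700, min_genes = 5,
                        reps = 100, seed = s)
    fit$score$z_sigma
  }, numeric(1))
  expect_true(all(abs(zs) < 4))
  expect_lt(mean(abs(zs) >= 3), 0.2)
})
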