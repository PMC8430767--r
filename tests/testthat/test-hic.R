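# Hi-C bin-pair classification, FDR filtering, stratification and the
# region-overlap enrichment test.

mini_hic_ann <- function() {
  genome_annotation(data.frame(name = c("chr1", "chr2"),
                               length_bp = c(1e7, 8e6),
                               centromere_bp = c(5e6, 4e6)))
}

test_that("bin pairs are canonicalised, validated and deduplicated", {
  ann <- mini_hic_ann()
  pairs <- data.frame(chrom_a = c("chr2", "chr1"), bin_start_a = c(0, 3e6),
                      chrom_b = c("chr1", "chr1"), bin_start_b = c(2e6, 1e6),
                      abundance = c(1, 2), logfc = c(0.5, -0.5),
                      p_value = c(0.1, 0.2))
  h <- hic_bin_pairs(pairs, annotation = ann)
  # both pairs arrive swapped and come back in canonical orientation
  expect_equal(h$pairs$chrom_a, c("chr1", "chr1"))
  expect_equal(h$pairs$bin_start_a, c(1e6, 2e6))
  expect_equal(h$pairs$chrom_b, c("chr1", "chr2"))
  expect_error(hic_bin_pairs(rbind(pairs, pairs[1, ]), annotation = ann),
               "duplicate")
  bad <- pairs; bad$bin_start_a[1] <- 1234
  expect_error(hic_bin_pairs(bad, annotation = ann), "multiples")
  # round trip through TSV
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hic_table(h, path)
  back <- read_hic_table(path, ann)
  expect_equal(back$pairs$p_value, h$pairs$p_value, tolerance = 1e-9)
})

test_that("classification partitions pairs and filters weak intra signals", {
  ann <- mini_hic_ann()
  pairs <- data.frame(
    chrom_a = c("chr1", "chr1", "chr1", "chr1", "chr1"),
    bin_start_a = c(0, 1e6, 2e6, 3e6, 4e6),
    chrom_b = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    bin_start_b = c(9e6, 2e6, 5e6, 0, 1e6),
    abundance = c(2, 0, 1, 0, 0.1),
    logfc = c(1, 1, -1, 1, -1),
    p_value = c(0.001, 0.001, 0.01, 0.02, 0.9))
  h <- hic_bin_pairs(pairs, annotation = ann)
  sig <- classify_and_filter(h, intra_fdr = 0.5, inter_fdr = 0.5)
  # same chromosome -> intra regardless of genomic distance
  expect_equal(sig$n_intra_tested, 2L)   # abundance 0 excluded (strict >)
  expect_equal(sig$n_inter_tested, 2L)
  expect_true(all(sig$intra$chrom_a == sig$intra$chrom_b))
  expect_true(all(sig$inter$chrom_a != sig$inter$chrom_b))
  expect_true(all(c(-1, 1) %in% sig$intra$direction) ||
                nrow(sig$intra) < 2)
  expect_error(classify_and_filter(h, 0, 0.5), "cutoffs")
})

test_that("BH adjustment matches the step-up oracle and is monotone in the cutoff", {
  ann <- mini_hic_ann()
  p <- c(0.001, 0.01, 0.02, 0.5, 0.9)
  pairs <- data.frame(chrom_a = "chr1", bin_start_a = (0:4) * 1e6,
                      chrom_b = "chr1", bin_start_b = (5:9) * 1e6,
                      abundance = 1, logfc = 1, p_value = p)
  h <- hic_bin_pairs(pairs, annotation = ann)
  sig <- classify_and_filter(h, intra_fdr = 0.999, inter_fdr = 0.5)
  expect_equal(sort(sig$intra$adj_p), sort(bh_stepup(p)), tolerance = 1e-12)
  # lowering the cutoff never adds significant pairs
  sizes <- vapply(c(0.9, 0.5, 0.1, 0.01),
                  function(cut) nrow(classify_and_filter(h, cut, 0.5)$intra),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("stratification counts intra once and inter at both endpoints", {
  ann <- mini_hic_ann()
  sig <- list(
    intra = data.frame(chrom_a = rep("chr1", 5), bin_start_a = (0:4) * 1e6,
                       chrom_b = rep("chr1", 5), bin_start_b = (5:9) * 1e6,
                       direction = c(1, 1, 1, -1, -1)),
    inter = data.frame(chrom_a = "chr1", bin_start_a = 0,
                       chrom_b = "chr2", bin_start_b = 0, direction = 1))
  st <- stratify_counts(sig, ann)
  expect_equal(st$intra_increased[st$chromosome == "chr1"], 3L)
  expect_equal(st$intra_decreased[st$chromosome == "chr1"], 2L)
  expect_equal(st$inter_endpoints, c(1L, 1L))
  empty <- list(intra = data.frame(), inter = data.frame())
  st0 <- stratify_counts(empty, ann)
  expect_true(all(st0$intra_increased == 0 & st0$inter_endpoints == 0))
})

test_that("overlap test equals hypergeometric enumeration on small tables", {
  # genome of 10 bins on one chromosome; 5 region bins; 5 significant bins
  # all inside the regions: one-sided p = 1 / C(10, 5) = 1/252
  ann <- genome_annotation(data.frame(name = "chr1", length_bp = 1e7,
                                      centromere_bp = 5e6))
  grcr_bins <- data.frame(chromosome = "chr1", bin_start = (0:4) * 1e6)
  sig <- data.frame(chrom_a = "chr1", bin_start_a = c(0, 1e6, 2e6, 3e6, 4e6),
                    chrom_b = "chr1", bin_start_b = c(0, 1e6, 2e6, 3e6, 4e6))
  ov <- overlap_fisher(sig, grcr_bins, ann)
  expect_equal(ov$fisher_p, 1 / 252, tolerance = 1e-12)
  expect_equal(unname(ov$contingency[1, ]), c(5L, 0L))
  # random small contingency tables against the enumeration oracle
  set.seed(13)
  for (i in 1:25) {
    m <- sample(1:10, 1); n_ <- sample(1:10, 1); k <- sample(1:(m + n_), 1)
    a <- max(0, k - n_):min(k, m)
    a <- sample(rep(a, 2), 1)
    tab <- matrix(c(a, k - a, m - a, n_ - (k - a)), 2, byrow = TRUE)
    expect_equal(stats::fisher.test(tab, alternative = "greater")$p.value,
                 fisher_greater_enum(tab[1, 1], tab[1, 2], tab[2, 1],
                                     tab[2, 2]),
                 tolerance = 1e-10)
  }
})

test_that("overlap test handles degenerate inputs and ignores labels", {
  ann <- mini_hic_ann()
  grcr_bins <- data.frame(chromosome = "chr1", bin_start = c(0, 1e6))
  none <- list(intra = data.frame(), inter = data.frame())
  ov0 <- overlap_fisher(none, grcr_bins, ann)
  expect_equal(ov0$fisher_p, 1)
  expect_true(ov0$degenerate)
  all_bins <- data.frame(chromosome = rep(c("chr1", "chr2"), c(10, 8)),
                         bin_start = c((0:9) * 1e6, (0:7) * 1e6))
  ovfull <- overlap_fisher(none, all_bins, ann)
  expect_true(ovfull$degenerate)
  # relabeling chromosomes leaves the p-value unchanged (counts only)
  sig <- data.frame(chrom_a = "chr1", bin_start_a = c(0, 2e6),
                    chrom_b = "chr1", bin_start_b = c(0, 2e6))
  p1 <- overlap_fisher(sig, grcr_bins, ann)$fisher_p
  ann2 <- genome_annotation(data.frame(name = c("k9", "k7"),
                                       length_bp = c(1e7, 8e6),
                                       centromere_bp = c(5e6, 4e6)))
  sig2 <- sig; sig2$chrom_a <- "k9"; sig2$chrom_b <- "k9"
  bins2 <- data.frame(chromosome = "k9", bin_start = c(0, 1e6))
  expect_equal(overlap_fisher(sig2, bins2, ann2)$fisher_p, p1)
})

test_that("planted Hi-C effects are detected as region enrichment", {
  ann <- sim_annotation(lengths_bp = c(chrA = 4e7, chrB = 4e7), seed = 2)
  regions <- data.frame(chrom = "chrA", start = 5e6, end = 1e7)
  grcr_bins <- data.frame(chromosome = "chrA", bin_start = (5:9) * 1e6)
  detected <- vapply(1:10, function(s) {
    h <- sim_hic_table(ann, enriched_regions = regions, n_planted = 8,
                       n_inter = 200, seed = 300 + s)
    sig <- classify_and_filter(h, intra_fdr = 0.1, inter_fdr = 0.2)
    overlap_fisher(sig, grcr_bins, ann)$fisher_p < 0.05
  }, logical(1))
  expect_gte(sum(detected), 9L)
})
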