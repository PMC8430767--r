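# Shared fixtures, built in code at test time.

# two hand-sized chromosomes with fully specified tracks, for feature and
# geometry tests where every expected value is computed by hand
tiny_annotation <- function() {
  genome_annotation(
    chromosomes = data.frame(name = c("chr1", "chr13"),
                             length_bp = c(5e7, 4e7),
                             centromere_bp = c(2e7, 1e7)),
    alu = data.frame(chrom = "chr1",
                     pos = c(1e6, 1e6 + 50000, 1e6 + 50001, 2e6)),
    replication = data.frame(chrom = c("chr1", "chr1", "chr13"),
                             start = c(0, 2e7, 0),
                             end = c(2e7, 5e7, 4e7),
                             timing = c(0.8, -0.4, 0)),
    cytobands = data.frame(chrom = c("chr1", "chr1", "chr1", "chr13"),
                           start = c(0, 2e7, 3e7, 0),
                           end = c(2e7, 3e7, 5e7, 4e7),
                           stain = c("gneg", "gpos50", "acen", "gvar")),
    tads = data.frame(chrom = "chr1", start = c(0, 1e6), end = c(1e6, 2e6),
                      tad_id = c("t1", "t2")),
    lads = data.frame(chrom = "chr1", start = 3e6, end = 4e6,
                      lad_id = "l1"))
}

# minimal table builder with sensible defaults
make_table <- function(gene_id, chromosome, start_bp, logfc,
                       avg_expr = rep(1, length(gene_id)),
                       p_value = rep(0.5, length(gene_id)),
                       label = "tab", annotation = NULL) {
  comparison_table(data.frame(gene_id = gene_id, chromosome = chromosome,
                              start_bp = start_bp, logfc = logfc,
                              avg_expr = avg_expr, p_value = p_value),
                   label = label, annotation = annotation)
}

# small genome for fast simulation-driven tests
small_genome <- function() c(chrA = 8e7, chrB = 6e7, chrC = 5e7)

small_sim_annotation <- function(seed = 1) {
  sim_annotation(lengths_bp = small_genome(), seed = seed)
}

# independent Benjamini-Hochberg step-up oracle
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# independent one-sided hypergeometric enumeration for a 2x2 table
# [[a, b], [c, d]]: P(X >= a) with X ~ Hypergeom
fisher_greater_enum <- function(a, b, c, d) {
  m <- a + c          # in-region bins
  n_ <- b + d         # out-region bins
  k <- a + b          # significant bins
  xs <- max(0, k - n_):min(k, m)
  probs <- choose(m, xs) * choose(n_, k - xs) / choose(m + n_, k)
  sum(probs[xs >= a])
}
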