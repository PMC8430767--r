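# The central fitting function: one call runs the full region analysis for
# a pair of differential-expression comparisons and returns a classed
# result object.

#' Compare two differential-expression comparisons for region-driven
#' positional correlation
#'
#' Runs the complete region analysis for one pair of comparisons: top-N
#' selection by absolute logFC, projection onto overlapping genomic windows
#' with expression-weighted averaging, Spearman correlation of the two
#' traces, a paired location-permutation null, and the sigma-difference
#' score.  A large difference between the actual and the permutation-
#' expected coefficient indicates that the differential expression common to
#' the two comparisons is carried by chromosomal regions rather than by
#' shared single genes; a small difference indicates conservation at the
#' single-gene level only (which survives the permutation because pairing is
#' preserved).
#'
#' @param table_a,table_b [comparison_table()]s.
#' @param annotation a [genome_annotation()].
#' @param top_n number of top genes by |logFC| (default 2000).
#' @param step_bp window spacing in bp (default 5,000,000).
#' @param window_bp window width in bp (default 10,000,000).
#' @param min_genes minimal genes per retained bin (default 10).
#' @param reps permutations for the null (default 1000).
#' @param seed integer seed for the permutation null.
#' @param weighted use expression-weighted bin means (default TRUE).
#' @return object of class `grcr` with components `actual` (the
#'   correlation), `null`, `score`, `trace_a`, `trace_b`, `bins` (the
#'   1 Mb-projected region bin set), and `params`.
#' @examples
#' ann <- sim_annotation(lengths_bp = c(chrA = 6e7, chrB = 6e7), seed = 1)
#' spec <- simulation_spec(n_genes = 2500, n_sites = 12, seed = 1)
#' pair <- plant_grcr_sites(sim_background_pair(ann, spec), ann, spec)$tables
#' fit <- grcr_compare(pair$a, pair$b, ann, min_genes = 5, reps = 50, seed = 1)
#' print(fit)
#' @export
grcr_compare <- function(table_a, table_b, annotation, top_n = 2000L,
                         step_bp = 5e6, window_bp = 1e7, min_genes = 10L,
                         reps = 1000L, seed, weighted = TRUE) {
  trace_a <- bin_trace(select_top_n(table_a, top_n), annotation,
                       step_bp, window_bp, min_genes, weighted)
  trace_b <- bin_trace(select_top_n(table_b, top_n), annotation,
                       step_bp, window_bp, min_genes, weighted)
  actual <- spearman_correlate(trace_a, trace_b)
  null <- shuffle_null(table_a, table_b, annotation, reps = reps, seed = seed,
                       top_n = top_n, step_bp = step_bp,
                       window_bp = window_bp, min_genes = min_genes,
                       weighted = weighted)
  score <- grcr_score(actual, null)
  structure(list(actual = actual, null = null, score = score,
                 trace_a = trace_a, trace_b = trace_b,
                 bins = grcr_bin_set(trace_a, trace_b),
                 params = list(top_n = top_n, step_bp = step_bp,
                               window_bp = window_bp, min_genes = min_genes,
                               reps = reps, seed = seed, weighted = weighted),
                 call = match.call()),
            class = "grcr")
}

#' @export
print.grcr <- function(x, ...) {
  cat("Region-driven correlation analysis:", x$actual$label_a, "~",
      x$actual$label_b, "\n")
  if (is.na(x$actual$rho)) {
    cat("  correlation undefined:", x$actual$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("  actual rho      %.3f over %d shared bins\n",
              x$actual$rho, x$actual$n_shared_bins))
  cat(sprintf("  expected rho    %.3f (permutation sd %.3f, %d reps)\n",
              x$null$rho_mean, x$null$rho_sd, x$null$reps))
  cat(sprintf("  difference      %.3f = %.2f sigma (normal tail %.3g, perm p %.3g)\n",
              x$score$diff, x$score$z_sigma, x$score$tail_prob,
              x$score$empirical_p))
  cat(sprintf("  shared genes    %.1f%% of contributing genes\n",
              100 * x$actual$shared_gene_fraction))
  cat(sprintf("  region bins     %d target bins on %d chromosome(s)\n",
              nrow(x$bins), length(unique(x$bins$chromosome))))
  invisible(x)
}

#' @export
summary.grcr <- function(object, ...) {
  out <- data.frame(
    label_a = object$actual$label_a,
    label_b = object$actual$label_b,
    rho_actual = object$actual$rho,
    rho_expected = object$null$rho_mean,
    rho_sd_null = object$null$rho_sd,
    diff = object$score$diff,
    z_sigma = object$score$z_sigma,
    tail_prob = object$score$tail_prob,
    empirical_p = object$score$empirical_p,
    n_shared_bins = object$actual$n_shared_bins,
    shared_gene_fraction = as.numeric(object$actual$shared_gene_fraction),
    n_region_bins = nrow(object$bins))
  class(out) <- c("summary.grcr", "data.frame")
  out
}

#' Plot a fitted region comparison
#'
#' Left panel: the two binned traces along the 1D genome concatenation.
#' Right panel: the permutation null distribution with the actual
#' coefficient marked.
#'
#' @param x a `grcr` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.grcr <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  ta <- x$trace_a$bins; tb <- x$trace_b$bins
  idx_a <- seq_len(nrow(ta)); idx_b <- seq_len(nrow(tb))
  graphics::plot(idx_a, ta$value, type = "p", pch = 16, col = "firebrick",
                 xlab = "retained bin (genome order)",
                 ylab = "weighted mean logFC",
                 main = "binned traces", ...)
  graphics::points(idx_b, tb$value, pch = 1, col = "steelblue")
  graphics::legend("topright", legend = c(x$trace_a$label, x$trace_b$label),
                   col = c("firebrick", "steelblue"), pch = c(16, 1),
                   bty = "n", cex = 0.8)
  s <- x$null$rho_samples
  if (!is.null(s) && sum(!is.na(s)) > 1) {
    graphics::hist(s[!is.na(s)], breaks = 30, col = "grey85", border = "white",
                   xlab = "null Spearman rho", main = "permutation null",
                   xlim = range(c(s, x$actual$rho), na.rm = TRUE))
    graphics::abline(v = x$actual$rho, col = "firebrick", lwd = 2)
  }
  invisible(x)
}
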