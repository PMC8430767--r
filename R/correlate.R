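# The region statistic: Spearman correlation between binned traces, the
# paired location-permutation null, and the sigma-difference score.

#' Spearman correlation between two binned traces
#'
#' Correlates the weighted bin averages of two traces over the intersection
#' of their retained windows.  Ranks use average ties; the two-sided p-value
#' comes from the standard large-sample t approximation.  With fewer than
#' three shared bins the coefficient is undefined and a reason code is
#' returned instead.
#'
#' @param trace_a,trace_b [bin_trace()] results built with identical binning
#'   parameters.
#' @return object of class `grcr_cor` with elements `label_a`, `label_b`,
#'   `rho`, `n_shared_bins`, `p_value`, `adj_p` (NA until a run-level BH
#'   pass fills it), `shared_gene_fraction` and, when undefined, `reason`.
#' @export
spearman_correlate <- function(trace_a, trace_b) {
  stopifnot(inherits(trace_a, "binned_trace"), inherits(trace_b, "binned_trace"))
  if (!identical(trace_a$params, trace_b$params))
    stop("traces were built with different binning parameters")
  shared <- intersect(trace_a$keys, trace_b$keys)
  out <- list(label_a = trace_a$label, label_b = trace_b$label,
              rho = NA_real_, n_shared_bins = length(shared),
              p_value = NA_real_, adj_p = NA_real_,
              shared_gene_fraction = shared_gene_fraction(trace_a, trace_b),
              reason = NULL)
  if (length(shared) < 3L) {
    out$reason <- "fewer than 3 shared bins"
    return(structure(out, class = "grcr_cor"))
  }
  va <- trace_a$bins$value[match(shared, trace_a$keys)]
  vb <- trace_b$bins$value[match(shared, trace_b$keys)]
  n <- length(shared)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    out$reason <- "constant trace values"
    return(structure(out, class = "grcr_cor"))
  }
  rho <- stats::cor(rank(va), rank(vb))
  out$rho <- rho
  if (abs(rho) >= 1) {
    out$p_value <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    out$p_value <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(out, class = "grcr_cor")
}

#' @export
print.grcr_cor <- function(x, ...) {
  if (is.na(x$rho)) {
    cat("Correlation ", x$label_a, " ~ ", x$label_b, ": undefined (",
        x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("Correlation %s ~ %s: rho = %.3f over %d shared bins (p = %.3g)\n",
                x$label_a, x$label_b, x$rho, x$n_shared_bins, x$p_value))
  }
  invisible(x)
}

#' Benjamini-Hochberg adjustment across the correlations of one run
#'
#' The adjustment family is all pairwise correlation results computed in
#' one run.  Undefined results (no rho) keep an NA adjusted value and do
#' not enter the family.
#'
#' @param cors list of `grcr_cor` objects from [spearman_correlate()].
#' @return the list with each element's `adj_p` filled.
#' @export
adjust_correlations <- function(cors) {
  stopifnot(all(vapply(cors, inherits, logical(1), "grcr_cor")))
  ps <- vapply(cors, function(x) x$p_value, numeric(1))
  adj <- rep(NA_real_, length(ps))
  ok <- !is.na(ps)
  adj[ok] <- stats::p.adjust(ps[ok], method = "BH")
  for (i in seq_along(cors)) cors[[i]]$adj_p <- adj[i]
  cors
}

#' Fraction of genes shared between the contributing sets of two traces
#'
#' The Jaccard fraction |intersection| / |union| of the gene ids that
#' contribute to at least one retained bin of each trace.  A small fraction
#' together with a large actual correlation indicates that the correlation
#' is carried by regions, not by identical genes.
#'
#' @param trace_a,trace_b [bin_trace()] results.
#' @return a number in \[0, 1\], or NA with attribute `reason` when both
#'   contributor sets are empty.
#' @export
shared_gene_fraction <- function(trace_a, trace_b) {
  ga <- unique(unlist(trace_a$contributors))
  gb <- unique(unlist(trace_b$contributors))
  if (length(ga) == 0L && length(gb) == 0L)
    return(structure(NA_real_, reason = "both contributor sets empty"))
  length(intersect(ga, gb)) / length(union(ga, gb))
}

#' Location-permutation null of the binned correlation
#'
#' Estimates the correlation expected when co-location is destroyed but
#' gene pairing is preserved: per repetition one permutation of the
#' (chromosome, position) labels is drawn over the union gene list of both
#' tables, a gene present in both tables receives the same new location in
#' both, and the full pipeline (top-N selection, binning, Spearman
#' correlation) is applied to the shuffled pair.  Because selection by
#' |logFC| is invariant under a location permutation, the selected gene sets
#' are precomputed and only locations are permuted per repetition; this is
#' an exact shortcut, not an approximation.
#'
#' @param table_a,table_b [comparison_table()]s sharing (at least partially)
#'   a gene-id universe.
#' @param annotation a [genome_annotation()].
#' @param reps number of permutations (default 1000).
#' @param seed integer seed.
#' @param top_n,step_bp,window_bp,min_genes,weighted pipeline parameters,
#'   see [select_top_n()] and [bin_trace()].
#' @param keep_samples store the per-repetition coefficients (needed for the
#'   empirical permutation p-value).
#' @return object of class `grcr_null` with `reps`, `rho_mean`, `rho_sd`,
#'   `rho_samples`, `n_undefined` and `seed`.
#' @export
shuffle_null <- function(table_a, table_b, annotation, reps = 1000L, seed,
                         top_n = 2000L, step_bp = 5e6, window_bp = 1e7,
                         min_genes = 10L, weighted = TRUE,
                         keep_samples = TRUE) {
  if (reps < 1L) stop("parameter error: reps must be >= 1")
  stopifnot(inherits(table_a, "comparison_table"),
            inherits(table_b, "comparison_table"))
  ga <- table_a$genes; gb <- table_b$genes
  u <- union(ga$gene_id, gb$gene_id)
  loc_src_a <- match(u, ga$gene_id)
  loc_src_b <- match(u, gb$gene_id)
  chrom <- ifelse(is.na(loc_src_a), gb$chromosome[loc_src_b],
                  ga$chromosome[loc_src_a])
  pos <- ifelse(is.na(loc_src_a), gb$start_bp[loc_src_b],
                ga$start_bp[loc_src_a])
  geom <- window_geometry(annotation, step_bp, window_bp)
  chrom_idx <- match(chrom, names(geom$lens))
  winmat <- covering_windows(chrom_idx, pos, geom)

  top_ids <- function(g) {
    if (nrow(g) <= top_n) return(g$gene_id)
    g$gene_id[sort(order(-abs(g$logfc), g$gene_id)[seq_len(top_n)])]
  }
  ida <- top_ids(ga); idb <- top_ids(gb)
  ua <- match(ida, u); ub <- match(idb, u)
  vala <- ga$logfc[match(ida, ga$gene_id)]
  valb <- gb$logfc[match(idb, gb$gene_id)]
  wa <- if (weighted) ga$avg_expr[match(ida, ga$gene_id)] else rep(1, length(ida))
  wb <- if (weighted) gb$avg_expr[match(idb, gb$gene_id)] else rep(1, length(idb))

  n_u <- length(u)
  samples <- numeric(reps)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      perm <- sample.int(n_u)
      agg_a <- aggregate_bins(winmat[perm[ua], , drop = FALSE], vala, wa, min_genes)
      agg_b <- aggregate_bins(winmat[perm[ub], , drop = FALSE], valb, wb, min_genes)
      shared <- intersect(agg_a$keys, agg_b$keys)
      samples[r] <- if (length(shared) < 3L) NA_real_ else
        suppressWarnings(
          stats::cor(rank(agg_a$value[match(shared, agg_a$keys)]),
                     rank(agg_b$value[match(shared, agg_b$keys)])))
    }
  })
  ok <- !is.na(samples)
  structure(list(reps = as.integer(reps),
                 rho_mean = mean(samples[ok]),
                 rho_sd = if (sum(ok) > 1L) stats::sd(samples[ok]) else 0,
                 rho_samples = if (keep_samples) samples else NULL,
                 n_undefined = sum(!ok),
                 seed = seed),
            class = "grcr_null")
}

#' @export
print.grcr_null <- function(x, ...) {
  cat(sprintf("Location-permutation null: %d reps, expected rho = %.3f (sd %.3f)",
              x$reps, x$rho_mean, x$rho_sd), "\n")
  if (x$n_undefined > 0L)
    cat("  ", x$n_undefined, "repetition(s) undefined (< 3 shared bins)\n")
  invisible(x)
}

#' Score an observed correlation against its permutation null
#'
#' The effect measure is the difference between the actual coefficient and
#' the permutation mean, expressed in multiples of the permutation standard
#' deviation (sigma).  The tail probability is the two-sided standard-normal
#' mass beyond |sigma| (0.27% at 3 sigma); when the permutation draws are
#' stored, the empirical one-sided permutation p-value
#' (1 + #{draws >= actual}) / (reps + 1) is reported alongside.
#'
#' @param actual a `grcr_cor` from [spearman_correlate()].
#' @param null a `grcr_null` from [shuffle_null()].
#' @return object of class `grcr_score` with `rho_actual`, `rho_expected`,
#'   `diff` (actual - expected), `z_sigma`, `tail_prob`, `empirical_p` and a
#'   `degenerate` flag when the null SD is zero.
#' @export
grcr_score <- function(actual, null) {
  stopifnot(inherits(actual, "grcr_cor"), inherits(null, "grcr_null"))
  if (null$rho_sd < 0) stop("null SD must be >= 0")
  d <- actual$rho - null$rho_mean
  degenerate <- FALSE
  if (is.na(d)) {
    z <- NA_real_
  } else if (d == 0) {
    z <- 0
  } else if (null$rho_sd == 0) {
    z <- sign(d) * Inf
    degenerate <- TRUE
  } else {
    z <- d / null$rho_sd
  }
  tail_prob <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))
  empirical_p <- NA_real_
  if (!is.null(null$rho_samples) && !is.na(actual$rho)) {
    s <- null$rho_samples[!is.na(null$rho_samples)]
    empirical_p <- (1 + sum(s >= actual$rho)) / (length(s) + 1)
  }
  structure(list(rho_actual = actual$rho, rho_expected = null$rho_mean,
                 diff = d, z_sigma = z, tail_prob = tail_prob,
                 empirical_p = empirical_p, degenerate = degenerate),
            class = "grcr_score")
}

#' @export
print.grcr_score <- function(x, ...) {
  cat(sprintf(
    "Region score: actual rho %.3f vs expected %.3f (diff %.3f = %.2f sigma)\n",
    x$rho_actual, x$rho_expected, x$diff, x$z_sigma))
  cat(sprintf("  normal tail prob %.4g; empirical permutation p %.4g\n",
              x$tail_prob, x$empirical_p))
  if (x$degenerate) cat("  note: null SD is zero; sigma reported as infinite\n")
  invisible(x)
}

#' Project windows retained in both traces onto a fixed bin tiling
#'
#' The detected regions are the windows retained in both traces; per
#' chromosome these are merged into maximal regions and projected onto a
#' `target_bin_bp` tiling: every target bin overlapping a region by at least
#' one bp is included.  The result is the bin set used by the Hi-C overlap
#' test.
#'
#' @param trace_a,trace_b [bin_trace()] results from the same annotation.
#' @param target_bin_bp target tiling bin size (default 1,000,000).
#' @return data.frame with columns `chromosome` and `bin_start`.
#' @export
grcr_bin_set <- function(trace_a, trace_b, target_bin_bp = 1e6) {
  stopifnot(inherits(trace_a, "binned_trace"), inherits(trace_b, "binned_trace"))
  shared <- intersect(trace_a$keys, trace_b$keys)
  empty <- data.frame(chromosome = character(0), bin_start = numeric(0))
  if (length(shared) == 0L) return(empty)
  i <- match(shared, trace_a$keys)
  b <- trace_a$bins[i, , drop = FALSE]
  # the truncated window end is recoverable from the stored midpoint
  b$end <- 2 * b$window_mid - b$window_start
  out <- empty
  for (chrom in unique(b$chromosome)) {
    bc <- b[b$chromosome == chrom, , drop = FALSE]
    merged <- merge_intervals(bc$window_start, bc$end)
    for (r in seq_len(nrow(merged))) {
      first <- floor(merged[r, 1L] / target_bin_bp)
      last <- ceiling(merged[r, 2L] / target_bin_bp) - 1
      out <- rbind(out, data.frame(chromosome = chrom,
                                   bin_start = (first:last) * target_bin_bp))
    }
  }
  rownames(out) <- NULL
  out
}
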