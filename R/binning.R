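# Top-N selection and the 1D binned projection of fold changes.

#' Select the top N differentially regulated genes
#'
#' Keeps the `n` genes of largest absolute logFC (all genes when the table
#' is smaller).  Ties at the boundary are broken by lexicographic gene id so
#' the selection is deterministic.  A relative cutoff of this kind makes
#' comparisons with very different overall fold-change intensity
#' commensurable.
#'
#' @param table a [comparison_table()].
#' @param n number of genes to keep (default 2000).
#' @return a [comparison_table()] restricted to the selected genes (canonical
#'   genomic order preserved).
#' @export
select_top_n <- function(table, n = 2000L) {
  stopifnot(inherits(table, "comparison_table"))
  if (n < 1L) stop("parameter error: n must be >= 1")
  g <- table$genes
  if (nrow(g) == 0L) {
    warning("empty comparison table")
    return(table)
  }
  if (nrow(g) > n) {
    o <- order(-abs(g$logfc), g$gene_id)
    keep <- sort(o[seq_len(n)])
    table$genes <- g[keep, , drop = FALSE]
    rownames(table$genes) <- NULL
  }
  table
}

# Precompute the window geometry of an annotation for a given binning:
# per-chromosome window starts (anchored at 0, step `step_bp`, width
# `window_bp`, truncated at the chromosome end) and a global window index.
window_geometry <- function(annotation, step_bp, window_bp) {
  if (step_bp <= 0) stop("parameter error: step_bp must be positive")
  if (window_bp < step_bp) stop("parameter error: window_bp must be >= step_bp")
  lens <- chrom_lengths(annotation)
  n_win <- as.integer(floor((lens - 1) / step_bp)) + 1L
  offset <- c(0L, cumsum(n_win))[seq_along(lens)]
  names(offset) <- names(lens)
  list(lens = lens, n_win = n_win, offset = offset,
       step_bp = step_bp, window_bp = window_bp,
       n_total = sum(n_win),
       max_cover = as.integer(ceiling(window_bp / step_bp)))
}

# Global window ids covering each position: an n x max_cover integer matrix
# with NA for non-covering slots.  chrom_idx indexes geometry$lens.
covering_windows <- function(chrom_idx, pos, geom) {
  k1 <- pos %/% geom$step_bp
  out <- matrix(NA_integer_, length(pos), geom$max_cover)
  for (off in seq_len(geom$max_cover) - 1L) {
    k <- k1 - off
    valid <- k >= 0 & k * geom$step_bp + geom$window_bp > pos
    out[valid, off + 1L] <- as.integer(geom$offset[chrom_idx[valid]] + k[valid] + 1L)
  }
  out
}

# Aggregate (value, weight) pairs into retained window bins.  Returns a list
# with global window keys, weighted means and gene counts.
aggregate_bins <- function(win_ids, values, weights, min_genes) {
  keep <- !is.na(win_ids)
  ids <- win_ids[keep]
  v <- rep(values, ncol(win_ids))[keep]
  w <- rep(weights, ncol(win_ids))[keep]
  if (!length(ids))
    return(list(keys = integer(0), value = numeric(0), n_genes = integer(0)))
  f <- factor(ids)
  sw <- rowsum(w, f)
  swv <- rowsum(w * v, f)
  cnt <- as.integer(rowsum(rep(1L, length(ids)), f))
  keys <- as.integer(levels(f))
  ok <- cnt >= min_genes & sw[, 1L] > 0
  list(keys = keys[ok], value = (swv[, 1L] / sw[, 1L])[ok],
       n_genes = cnt[ok], n_zero_weight = sum(cnt >= min_genes & sw[, 1L] <= 0))
}

#' Project a comparison table onto overlapping genomic windows
#'
#' Bins genes per chromosome into windows anchored at coordinate 0, spaced
#' `step_bp` apart and `window_bp` wide (the 10 Mb / 5 Mb defaults give a
#' 2x oversampling that removes dependence on an arbitrary window border).
#' A gene contributes to every window containing its start position.  The
#' bin value is the expression-weighted mean logFC, sum(logfc * avg_expr) /
#' sum(avg_expr); bins with fewer than `min_genes` contributing genes are
#' dropped, as are bins with zero total weight (with a warning).
#'
#' @param table a [comparison_table()] (typically after [select_top_n()]).
#' @param annotation a [genome_annotation()].
#' @param step_bp distance between window starts (default 5,000,000).
#' @param window_bp window width (default 10,000,000).
#' @param min_genes minimal number of genes for a bin to be retained
#'   (default 10; subset analyses use 5).
#' @param weighted if FALSE, use the unweighted mean logFC instead.
#' @return object of class `binned_trace`: the comparison label, a
#'   data.frame of retained bins (chromosome, window_start, window_mid,
#'   value, n_genes), contributing gene ids per bin, and the binning
#'   parameters.
#' @export
bin_trace <- function(table, annotation, step_bp = 5e6, window_bp = 1e7,
                      min_genes = 10L, weighted = TRUE) {
  stopifnot(inherits(table, "comparison_table"),
            inherits(annotation, "genome_annotation"))
  if (min_genes < 1L) stop("parameter error: min_genes must be >= 1")
  geom <- window_geometry(annotation, step_bp, window_bp)
  g <- table$genes
  chrom_idx <- match(g$chromosome, names(geom$lens))
  if (anyNA(chrom_idx))
    stop("table contains chromosomes absent from the annotation")
  win <- covering_windows(chrom_idx, g$start_bp, geom)
  weights <- if (weighted) g$avg_expr else rep(1, nrow(g))
  agg <- aggregate_bins(win, g$logfc, weights, min_genes)
  if (!is.null(agg$n_zero_weight) && agg$n_zero_weight > 0L)
    warning(agg$n_zero_weight, " bin(s) dropped: zero total weight")
  contributors <- list()
  if (length(agg$keys)) {
    keep <- !is.na(win)
    ids <- win[keep]
    gid <- rep(g$gene_id, ncol(win))[keep]
    sel <- ids %in% agg$keys
    contributors <- split(gid[sel], factor(ids[sel], levels = agg$keys))
  }
  # map global window keys back to (chromosome, start)
  chrom_of <- findInterval(agg$keys - 1L, c(0L, cumsum(geom$n_win)),
                           rightmost.closed = FALSE)
  start <- (agg$keys - 1L - geom$offset[chrom_of]) * step_bp
  end <- pmin(start + window_bp, geom$lens[chrom_of])
  bins <- data.frame(chromosome = names(geom$lens)[chrom_of],
                     window_start = start,
                     window_mid = (start + end) / 2,
                     value = agg$value,
                     n_genes = agg$n_genes,
                     row.names = NULL)
  structure(list(label = table$label, bins = bins,
                 contributors = unname(contributors), keys = agg$keys,
                 params = list(step_bp = step_bp, window_bp = window_bp,
                               min_genes = min_genes, weighted = weighted)),
            class = "binned_trace")
}

#' @export
print.binned_trace <- function(x, ...) {
  cat("Binned trace '", x$label, "': ", nrow(x$bins), " retained bins (",
      "window ", x$params$window_bp, " bp, step ", x$params$step_bp,
      " bp, min ", x$params$min_genes, " genes)\n", sep = "")
  invisible(x)
}
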