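# Structural chromatin features per gene and the subset correlation
# analysis: the same region statistic computed independently on two
# feature-defined gene subsets.

# chromosome-size classes used throughout: the largest mid-range length gap
# of the human assembly lies between chr12 and chr13
LONG_CHROMS <- c(paste0("chr", 1:12), "chrX")
SHORT_CHROMS <- c(paste0("chr", 13:22), "chrY")

# interval membership: value of the covering half-open interval, NA outside.
# `track` has columns chrom, start, end; intervals non-overlapping per chrom.
interval_value <- function(chrom, pos, track, value_col) {
  out <- rep(NA, length(pos))
  if (nrow(track) == 0L) return(out)
  for (cn in unique(chrom)) {
    tr <- track[track$chrom == cn, , drop = FALSE]
    sel <- which(chrom == cn)
    if (nrow(tr) == 0L) next
    i <- findInterval(pos[sel], tr$start)
    hit <- i >= 1L & pos[sel] < tr$end[pmax(i, 1L)]
    out[sel[hit]] <- tr[[value_col]][i[hit]]
  }
  out
}

#' Annotate genes with structural chromatin features
#'
#' Computes, per gene: the chromosome size class (long = chr1-chr12 and
#' chrX, short = chr13-chr22 and chrY); the arm region (within the outer 1/5
#' of the p arm measured from the p telomere, the outer 1/5 of the q arm
#' measured from the q telomere, or interior); the Alu element count within
#' +/- `alu_halfwindow_bp` on the same chromosome; the replication timing
#' index of the covering domain; the cytoband stain sign (negative for
#' gneg; positive for gpos25/50/75/100 and gvar; excluded otherwise, e.g.
#' acen and stalk); the covering TAD id; and the LAD flag (inside an LAD or
#' within `lad_margin_bp` of one).  Features whose track is absent from the
#' annotation are returned as NA, never defaulted.
#'
#' @param table a [comparison_table()].
#' @param annotation a [genome_annotation()].
#' @param alu_halfwindow_bp half-window for the Alu count (default 50,000,
#'   i.e. a 100 kb total window; configurable because published window
#'   conventions differ).
#' @param lad_margin_bp LAD neighbourhood margin (default 10,000).
#' @return data.frame with one row per gene: `gene_id`, `chromosome`,
#'   `chrom_class`, `arm_region`, `alu_count`, `rep_index`,
#'   `cytoband_sign`, `cytoband_id`, `tad_id`, `lad_id` (covering LAD,
#'   margin not applied) and `lad_flag` (margin applied).  The Alu
#'   half-window used is kept as attribute `alu_halfwindow_bp`.
#' @export
annotate_features <- function(table, annotation, alu_halfwindow_bp = 50000,
                              lad_margin_bp = 10000) {
  stopifnot(inherits(table, "comparison_table"),
            inherits(annotation, "genome_annotation"))
  g <- table$genes
  chroms <- annotation$chromosomes
  ci <- match(g$chromosome, chroms$name)
  cen <- chroms$centromere_bp[ci]
  len <- chroms$length_bp[ci]

  chrom_class <- ifelse(g$chromosome %in% LONG_CHROMS, "long",
                        ifelse(g$chromosome %in% SHORT_CHROMS, "short",
                               NA_character_))
  # fall back to a length-median split for non-human chromosome names so
  # synthetic genomes with other naming stay analysable
  if (all(is.na(chrom_class)) && nrow(chroms) > 1L) {
    med <- stats::median(chroms$length_bp)
    chrom_class <- ifelse(len >= med, "long", "short")
  }

  p_end <- g$start_bp < cen / 5
  q_end <- g$start_bp >= len - (len - cen) / 5
  arm_region <- ifelse(p_end, "p_end", ifelse(q_end, "q_end", "interior"))

  alu_count <- rep(NA_integer_, nrow(g))
  if (nrow(annotation$alu)) {
    alu_count <- integer(nrow(g))
    for (cn in unique(g$chromosome)) {
      apos <- annotation$alu$pos[annotation$alu$chrom == cn]
      sel <- which(g$chromosome == cn)
      alu_count[sel] <- findInterval(g$start_bp[sel] + alu_halfwindow_bp, apos) -
        findInterval(g$start_bp[sel] - alu_halfwindow_bp - 1, apos)
    }
  }

  rep_index <- as.numeric(interval_value(g$chromosome, g$start_bp,
                                         annotation$replication, "timing"))
  stain <- as.character(interval_value(g$chromosome, g$start_bp,
                                       annotation$cytobands, "stain"))
  cytoband_sign <- ifelse(is.na(stain), NA_character_,
                          ifelse(stain == "gneg", "negative",
                                 ifelse(stain %in% c("gpos25", "gpos50", "gpos75",
                                                     "gpos100", "gvar"),
                                        "positive", "excluded")))
  tad_id <- as.character(interval_value(g$chromosome, g$start_bp,
                                        annotation$tads, "tad_id"))
  band_track <- annotation$cytobands
  if (nrow(band_track))
    band_track$band_id <- paste0(band_track$chrom, ":", band_track$start)
  cytoband_id <- as.character(interval_value(g$chromosome, g$start_bp,
                                             band_track, "band_id"))
  lad_id <- as.character(interval_value(g$chromosome, g$start_bp,
                                        annotation$lads, "lad_id"))
  lad_flag <- rep(NA, nrow(g))
  if (nrow(annotation$lads)) {
    widened <- annotation$lads
    widened$start <- pmax(0, widened$start - lad_margin_bp)
    widened$end <- widened$end + lad_margin_bp
    # widening may create touching intervals; membership only needs any hit
    lad_flag <- logical(nrow(g))
    for (cn in unique(g$chromosome)) {
      tr <- widened[widened$chrom == cn, , drop = FALSE]
      sel <- which(g$chromosome == cn)
      if (nrow(tr) == 0L) { lad_flag[sel] <- FALSE; next }
      for (j in seq_len(nrow(tr)))
        lad_flag[sel] <- lad_flag[sel] |
          (g$start_bp[sel] >= tr$start[j] & g$start_bp[sel] < tr$end[j])
    }
  }
  n_uncovered <- sum(is.na(rep_index)) + sum(is.na(stain))
  if (n_uncovered > 0L && (nrow(annotation$replication) || nrow(annotation$cytobands)))
    message(n_uncovered, " gene-feature value(s) absent: position outside ",
            "all replication/cytoband intervals")
  structure(data.frame(gene_id = g$gene_id, chromosome = g$chromosome,
                       chrom_class = chrom_class,
                       arm_region = arm_region, alu_count = alu_count,
                       rep_index = rep_index, cytoband_sign = cytoband_sign,
                       cytoband_id = cytoband_id, tad_id = tad_id,
                       lad_id = lad_id, lad_flag = lad_flag,
                       stringsAsFactors = FALSE),
            alu_halfwindow_bp = alu_halfwindow_bp,
            lad_margin_bp = lad_margin_bp)
}

#' Split a comparison table into two feature-defined subsets
#'
#' Supported split keys: `chrom_class` (long vs short chromosomes),
#' `arm_region` (arm ends vs interior), `alu_rich` (more than
#' `alu_threshold` Alu elements within the annotation window vs at most
#' that many), `replication` (early, index > 0, vs late, index <= 0) and
#' `cytoband_sign` (positive vs negative stains; excluded stains dropped).
#' TAD and LAD splits are deliberately unsupported: membership is far too
#' unbalanced to give both subsets enough bins, so requesting them raises an
#' error.
#'
#' @param table a [comparison_table()].
#' @param features the [annotate_features()] result for (at least) the
#'   genes of `table`.
#' @param feature split key, see above.
#' @param alu_threshold count threshold of the `alu_rich` split (default 50).
#' @return list with the two subset tables (`high`, `low` in the order
#'   documented above) and `n_dropped`, the number of genes without a
#'   defined feature value.
#' @export
split_by_feature <- function(table, features, feature, alu_threshold = 50) {
  stopifnot(inherits(table, "comparison_table"))
  if (feature %in% c("tad", "lad", "tad_id", "lad_flag"))
    stop("unsupported split: TAD/LAD membership is too unbalanced to define ",
         "two subsets with enough bins")
  f <- features[match(table$genes$gene_id, features$gene_id), , drop = FALSE]
  cls <- switch(feature,
    chrom_class = ifelse(f$chrom_class == "long", "high",
                         ifelse(f$chrom_class == "short", "low", NA)),
    arm_region = ifelse(is.na(f$arm_region), NA,
                        ifelse(f$arm_region %in% c("p_end", "q_end"),
                               "high", "low")),
    alu_rich = ifelse(is.na(f$alu_count), NA,
                      ifelse(f$alu_count > alu_threshold, "high", "low")),
    replication = ifelse(is.na(f$rep_index), NA,
                         ifelse(f$rep_index > 0, "high", "low")),
    cytoband_sign = ifelse(is.na(f$cytoband_sign) |
                             f$cytoband_sign == "excluded", NA,
                           ifelse(f$cytoband_sign == "positive",
                                  "high", "low")),
    stop("parameter error: unknown split feature '", feature, "'"))
  n_dropped <- sum(is.na(cls))
  subset_tab <- function(which_cls, suffix) {
    t2 <- table
    t2$genes <- table$genes[!is.na(cls) & cls == which_cls, , drop = FALSE]
    rownames(t2$genes) <- NULL
    t2$label <- paste0(table$label, suffix)
    t2
  }
  list(high = subset_tab("high", paste0("|", feature, "+")),
       low = subset_tab("low", paste0("|", feature, "-")),
       n_dropped = n_dropped)
}

#' Region analysis on two feature-defined subsets
#'
#' Splits both comparisons by the same feature rule and runs the full
#' region analysis (top-N selection, binning, correlation, permutation
#' null, sigma score) independently per subset.  The default `min_genes`
#' is 5 here, accounting for the smaller gene density within subsets.  A
#' clear sigma difference in one subset but not the other indicates that
#' the region coupling depends on the structure analysed.  Bin counts are
#' reported so sparse subsets are not over-interpreted.
#'
#' @param table_a,table_b [comparison_table()]s.
#' @param features [annotate_features()] output covering the genes of both.
#' @param feature split key, see [split_by_feature()].
#' @param annotation a [genome_annotation()].
#' @param seed integer seed.
#' @param top_n,step_bp,window_bp,min_genes,reps pipeline parameters
#'   (min_genes default 5).
#' @return list with one element per subset (`high`, `low`), each a `grcr`
#'   fit (or a record with reason when a subset has fewer than 3 shared
#'   bins), plus `n_dropped`.
#' @export
subset_grcr_analysis <- function(table_a, table_b, features, feature,
                                 annotation, seed, top_n = 2000L,
                                 step_bp = 5e6, window_bp = 1e7,
                                 min_genes = 5L, reps = 1000L) {
  sa <- split_by_feature(table_a, features, feature)
  sb <- split_by_feature(table_b, features, feature)
  run <- function(ta, tb) {
    if (nrow(ta$genes) == 0L || nrow(tb$genes) == 0L)
      return(list(actual = structure(list(rho = NA_real_,
                                          reason = "empty subset"),
                                     class = "grcr_cor")))
    grcr_compare(ta, tb, annotation, top_n = top_n, step_bp = step_bp,
                 window_bp = window_bp, min_genes = min_genes, reps = reps,
                 seed = derive_seed(seed, paste0(feature, "_", ta$label)))
  }
  list(high = run(sa$high, sb$high),
       low = run(sa$low, sb$low),
       n_dropped = sa$n_dropped)
}
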