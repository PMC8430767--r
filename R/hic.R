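# Downstream differential Hi-C analysis: intra/inter classification and
# filtering, BH FDR significance calling, per-chromosome stratification,
# and the Fisher enrichment test of significant interaction bins toward
# the detected transcriptional regions.

#' Construct a Hi-C bin-pair table
#'
#' Holds the output of an upstream differential interaction test on
#' fixed-width bins: per pair the two bin anchors, the normalised
#' interaction abundance, the differential logFC and p-value.  Anchors are
#' canonically ordered ((chrom_a, bin_start_a) <= (chrom_b, bin_start_b) in
#' annotation chromosome order), must be multiples of the bin size, and
#' duplicate canonical pairs are rejected.
#'
#' @param pairs data.frame with columns `chrom_a`, `bin_start_a`,
#'   `chrom_b`, `bin_start_b`, `abundance`, `logfc`, `p_value` and
#'   optionally `adj_p`.
#' @param bin_bp bin size in bp (default 1e6).
#' @param annotation the [genome_annotation()] the bins tile.
#' @return object of class `hic_bin_pairs`.
#' @export
hic_bin_pairs <- function(pairs, bin_bp = 1e6, annotation) {
  req <- c("chrom_a", "bin_start_a", "chrom_b", "bin_start_b",
           "abundance", "logfc", "p_value")
  miss <- setdiff(req, names(pairs))
  if (length(miss))
    stop("format error: missing column(s): ", paste(miss, collapse = ", "))
  lens <- chrom_lengths(annotation)
  if (!all(pairs$chrom_a %in% names(lens)) ||
      !all(pairs$chrom_b %in% names(lens)))
    stop("bin pairs on chromosomes absent from the annotation")
  if (any(pairs$bin_start_a %% bin_bp != 0 | pairs$bin_start_b %% bin_bp != 0))
    stop("format error: bin starts must be multiples of the bin size")
  ra <- match(pairs$chrom_a, names(lens))
  rb <- match(pairs$chrom_b, names(lens))
  swap <- ra > rb | (ra == rb & pairs$bin_start_a > pairs$bin_start_b)
  if (any(swap)) {
    tmp_c <- pairs$chrom_a[swap]; tmp_s <- pairs$bin_start_a[swap]
    pairs$chrom_a[swap] <- pairs$chrom_b[swap]
    pairs$bin_start_a[swap] <- pairs$bin_start_b[swap]
    pairs$chrom_b[swap] <- tmp_c
    pairs$bin_start_b[swap] <- tmp_s
  }
  key <- paste(pairs$chrom_a, pairs$bin_start_a,
               pairs$chrom_b, pairs$bin_start_b)
  if (anyDuplicated(key)) stop("duplicate canonical bin pairs")
  o <- order(match(pairs$chrom_a, names(lens)), pairs$bin_start_a,
             match(pairs$chrom_b, names(lens)), pairs$bin_start_b)
  pairs <- pairs[o, , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, bin_bp = bin_bp, genome = annotation),
            class = "hic_bin_pairs")
}

#' @export
print.hic_bin_pairs <- function(x, ...) {
  intra <- sum(x$pairs$chrom_a == x$pairs$chrom_b)
  cat("Hi-C bin pairs:", nrow(x$pairs), "pairs (", intra, "intra,",
      nrow(x$pairs) - intra, "inter ) at", format(x$bin_bp, scientific = FALSE),
      "bp bins\n")
  invisible(x)
}

#' Read a Hi-C bin-pair table from tab-separated text
#'
#' @param path TSV with a header matching the [hic_bin_pairs()] columns.
#' @param annotation a [genome_annotation()].
#' @param bin_bp bin size in bp.
#' @return a [hic_bin_pairs()].
#' @export
read_hic_table <- function(path, annotation, bin_bp = 1e6) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  hic_bin_pairs(df, bin_bp = bin_bp, annotation = annotation)
}

#' Write a Hi-C bin-pair table to tab-separated text
#'
#' @param table a [hic_bin_pairs()].
#' @param path output path.
#' @export
write_hic_table <- function(table, path) {
  write_report_table(table$pairs, path)
}

#' Classify and filter differential Hi-C bin pairs
#'
#' Splits pairs into intrachromosomal (same chromosome) and
#' interchromosomal classes; intra pairs must additionally carry a strong
#' signal (abundance strictly greater than `abundance_min`, default 0) and
#' are excluded from testing otherwise.  Benjamini-Hochberg adjustment is
#' applied independently within each class; a pair is significant when its
#' adjusted p-value is at most the class cutoff.  A `direction` flag
#' (sign of logFC) is attached to the significant sets.
#'
#' @param table a [hic_bin_pairs()].
#' @param intra_fdr FDR cutoff for intra pairs (the study used 0.25 and
#'   0.1 for its two gravity comparisons).
#' @param inter_fdr FDR cutoff for inter pairs (0.33 and 0.2 in the study).
#' @param abundance_min intra abundance threshold (strict >; default 0).
#' @return list with data.frames `intra` and `inter` (significant pairs
#'   with `adj_p` and `direction` columns) and the tested pair counts
#'   `n_intra_tested`, `n_inter_tested`.
#' @export
classify_and_filter <- function(table, intra_fdr, inter_fdr,
                                abundance_min = 0) {
  stopifnot(inherits(table, "hic_bin_pairs"))
  if (intra_fdr <= 0 || intra_fdr >= 1 || inter_fdr <= 0 || inter_fdr >= 1)
    stop("parameter error: FDR cutoffs must lie in (0, 1)")
  p <- table$pairs
  intra <- p[p$chrom_a == p$chrom_b & p$abundance > abundance_min, , drop = FALSE]
  inter <- p[p$chrom_a != p$chrom_b, , drop = FALSE]
  sig <- function(df, cutoff) {
    if (nrow(df) == 0L) {
      df$adj_p <- numeric(0); df$direction <- numeric(0)
      return(df)
    }
    df$adj_p <- stats::p.adjust(df$p_value, method = "BH")
    df <- df[df$adj_p <= cutoff, , drop = FALSE]
    df$direction <- sign(df$logfc)
    rownames(df) <- NULL
    df
  }
  list(intra = sig(intra, intra_fdr), inter = sig(inter, inter_fdr),
       n_intra_tested = nrow(intra), n_inter_tested = nrow(inter))
}

#' Stratify significant bin pairs by chromosome
#'
#' Intra pairs are counted once on their chromosome and split by
#' interaction direction (increased: logFC > 0, decreased otherwise);
#' inter pairs contribute one endpoint count to each of their two
#' chromosomes.
#'
#' @param significant a [classify_and_filter()] result.
#' @param annotation a [genome_annotation()] fixing the chromosome order.
#' @return data.frame with columns `chromosome`, `intra_increased`,
#'   `intra_decreased`, `inter_endpoints`.
#' @export
stratify_counts <- function(significant, annotation) {
  chroms <- annotation$chromosomes$name
  out <- data.frame(chromosome = chroms,
                    intra_increased = 0L, intra_decreased = 0L,
                    inter_endpoints = 0L)
  si <- significant$intra
  if (nrow(si)) {
    up <- table(factor(si$chrom_a[si$direction > 0], levels = chroms))
    dn <- table(factor(si$chrom_a[si$direction <= 0], levels = chroms))
    out$intra_increased <- as.integer(up)
    out$intra_decreased <- as.integer(dn)
  }
  se <- significant$inter
  if (nrow(se)) {
    ends <- table(factor(c(se$chrom_a, se$chrom_b), levels = chroms))
    out$inter_endpoints <- as.integer(ends)
  }
  out
}

#' Fisher enrichment test of significant Hi-C bins toward region bins
#'
#' The tested unit is the unique set of bins that anchor at least one
#' significant pair (intra and inter pooled by default).  The 2x2
#' contingency table crosses membership in the region bin set against
#' significance: significant bins in/outside regions versus the remaining
#' genome bins in/outside regions ("all possible bins" = every `bin_bp`
#' tile of every annotation chromosome).  The p-value is the exact
#' hypergeometric tail; the default sidedness is `greater` because the
#' claim under test is a directional localisation bias towards the
#' regions.
#'
#' @param significant a [classify_and_filter()] result (or a data.frame of
#'   significant pairs).
#' @param grcr_bins data.frame (`chromosome`, `bin_start`) from
#'   [grcr_bin_set()].
#' @param annotation a [genome_annotation()].
#' @param bin_bp bin size in bp (must match `grcr_bins`).
#' @param sidedness `"greater"` (enrichment, default) or `"two_sided"`.
#' @param classes which significant classes to pool (default both).
#' @return object of class `hic_overlap`: `contingency` (2x2 matrix),
#'   `odds_ratio`, `fisher_p`, `sidedness`, `degenerate` flag.
#' @export
overlap_fisher <- function(significant, grcr_bins, annotation, bin_bp = 1e6,
                           sidedness = c("greater", "two_sided"),
                           classes = c("intra", "inter")) {
  sidedness <- match.arg(sidedness)
  lens <- chrom_lengths(annotation)
  n_bins <- pmax(1L, as.integer(ceiling(lens / bin_bp)))
  total_bins <- sum(n_bins)
  region_keys <- unique(paste(grcr_bins$chromosome, grcr_bins$bin_start))
  n_region <- length(region_keys)
  if (n_region >= total_bins) {
    return(structure(list(contingency = NULL, odds_ratio = NA_real_,
                          fisher_p = NA_real_, sidedness = sidedness,
                          degenerate = TRUE,
                          reason = "region bins cover the whole genome"),
                     class = "hic_overlap"))
  }
  sig_pairs <- if (is.data.frame(significant)) significant else
    do.call(rbind, lapply(classes, function(cl) {
      df <- significant[[cl]]
      if (is.null(df) || nrow(df) == 0L) NULL else
        df[, c("chrom_a", "bin_start_a", "chrom_b", "bin_start_b")]
    }))
  sig_keys <- if (is.null(sig_pairs) || nrow(sig_pairs) == 0L) character(0) else
    unique(c(paste(sig_pairs$chrom_a, sig_pairs$bin_start_a),
             paste(sig_pairs$chrom_b, sig_pairs$bin_start_b)))
  n_sig <- length(sig_keys)
  if (n_sig == 0L) {
    return(structure(list(contingency = matrix(c(0L, 0L, n_region,
                                                 total_bins - n_region), 2L,
                                               byrow = TRUE),
                          odds_ratio = NA_real_, fisher_p = 1,
                          sidedness = sidedness, degenerate = TRUE,
                          reason = "no significant bins"),
                     class = "hic_overlap"))
  }
  sig_in <- sum(sig_keys %in% region_keys)
  sig_out <- n_sig - sig_in
  rest_in <- n_region - sig_in
  rest_out <- (total_bins - n_region) - sig_out
  contingency <- matrix(c(sig_in, sig_out, rest_in, rest_out), 2L,
                        byrow = TRUE,
                        dimnames = list(c("significant", "other"),
                                        c("in_region", "out_region")))
  ft <- stats::fisher.test(contingency,
                           alternative = if (sidedness == "greater")
                             "greater" else "two.sided")
  structure(list(contingency = contingency,
                 odds_ratio = unname(ft$estimate),
                 fisher_p = ft$p.value, sidedness = sidedness,
                 degenerate = FALSE),
            class = "hic_overlap")
}

#' @export
print.hic_overlap <- function(x, ...) {
  cat("Hi-C bin / region overlap test (", x$sidedness, ")\n", sep = "")
  if (isTRUE(x$degenerate)) {
    cat("  degenerate:", x$reason, "; p =", x$fisher_p, "\n")
    return(invisible(x))
  }
  print(x$contingency)
  cat(sprintf("  odds ratio %.3g, Fisher p = %.3g\n", x$odds_ratio,
              x$fisher_p))
  invisible(x)
}
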