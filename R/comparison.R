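# Differential-expression comparison tables: one row per uniquely mapping
# gene with its genomic location, log2 fold change, average expression
# (used as a weight) and p-values.

#' Construct a differential-expression comparison table
#'
#' Validates per-gene records and, when an annotation is supplied, drops
#' genes on chromosomes absent from it (the drop count is reported and kept
#' as attribute `n_dropped`).  Rows are canonically sorted by chromosome
#' (annotation order), position and gene id so that input order never
#' influences downstream results.
#'
#' @param genes data.frame with columns `gene_id`, `chromosome`, `start_bp`
#'   (0-based), `logfc`, `avg_expr` (>= 0), `p_value` and optionally `adj_p`.
#' @param label character label for the comparison.
#' @param annotation optional [genome_annotation()] used for validation and
#'   chromosome ordering.
#' @param metadata free-form named list of provenance.
#' @return object of class `comparison_table` with elements `label`, `genes`
#'   and `metadata`.
#' @export
comparison_table <- function(genes, label = "comparison", annotation = NULL,
                             metadata = list()) {
  req <- c("gene_id", "chromosome", "start_bp", "logfc", "avg_expr", "p_value")
  miss <- setdiff(req, names(genes))
  if (length(miss))
    stop("format error: missing mandatory column(s): ", paste(miss, collapse = ", "))
  genes$gene_id <- as.character(genes$gene_id)
  genes$chromosome <- as.character(genes$chromosome)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id values: ",
         paste(utils::head(unique(genes$gene_id[duplicated(genes$gene_id)]), 3L),
               collapse = ", "))
  for (col in c("start_bp", "logfc", "avg_expr", "p_value"))
    if (!is.numeric(genes[[col]]))
      stop("parse error: non-numeric values in column ", col)
  if (any(genes$avg_expr < 0, na.rm = TRUE)) stop("avg_expr must be >= 0")
  if (any(genes$p_value < 0 | genes$p_value > 1, na.rm = TRUE))
    stop("p_value must lie in [0, 1]")
  n_dropped <- 0L
  if (!is.null(annotation)) {
    lens <- chrom_lengths(annotation)
    keep <- genes$chromosome %in% names(lens)
    keep[keep] <- genes$start_bp[keep] >= 0 &
      genes$start_bp[keep] < lens[genes$chromosome[keep]]
    n_dropped <- sum(!keep)
    if (n_dropped > 0L)
      message(n_dropped, " gene(s) dropped: unknown chromosome or position ",
              "outside chromosome bounds")
    genes <- genes[keep, , drop = FALSE]
    chrom_rank <- match(genes$chromosome, annotation$chromosomes$name)
  } else {
    chrom_rank <- match(genes$chromosome, order_chromosomes(unique(genes$chromosome)))
  }
  genes <- genes[order(chrom_rank, genes$start_bp, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  keep_cols <- c(req, if ("adj_p" %in% names(genes)) "adj_p")
  structure(list(label = label, genes = genes[, keep_cols, drop = FALSE],
                 metadata = metadata),
            class = "comparison_table", n_dropped = n_dropped)
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("Comparison table '", x$label, "': ", nrow(x$genes), " genes on ",
      length(unique(x$genes$chromosome)), " chromosomes\n", sep = "")
  cat("  |logFC| range: ",
      paste(signif(range(abs(x$genes$logfc)), 3), collapse = " .. "), "\n")
  invisible(x)
}

#' Read a comparison table from delimited text
#'
#' Expects a tab-separated file with a header containing `gene_id`,
#' `chromosome`, the position column (`start_bp` by default), `logfc`,
#' `avg_expr`, `p_value`, and optionally `adj_p`.  Non-numeric entries in
#' numeric columns are reported with their row index.
#'
#' @param path file path.
#' @param annotation optional [genome_annotation()]; genes on chromosomes
#'   absent from it are dropped with a logged count.
#' @param label comparison label (default: file name).
#' @param position_col name of the column holding the gene position.
#' @param one_based logical; if TRUE positions are converted to 0-based.
#' @return a [comparison_table()].
#' @export
read_comparison_table <- function(path, annotation = NULL,
                                  label = basename(path),
                                  position_col = "start_bp",
                                  one_based = FALSE) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  if (!position_col %in% names(raw))
    stop("format error: missing mandatory column(s): ", position_col)
  names(raw)[names(raw) == position_col] <- "start_bp"
  req <- c("gene_id", "chromosome", "start_bp", "logfc", "avg_expr", "p_value")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("format error: missing mandatory column(s): ", paste(miss, collapse = ", "))
  num_cols <- c("start_bp", "logfc", "avg_expr", "p_value",
                if ("adj_p" %in% names(raw)) "adj_p")
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !(raw[[col]] %in% c("NA", "")))
    if (length(bad))
      stop("parse error: non-numeric value in column '", col,
           "' at row ", bad[1L])
    raw[[col]] <- v
  }
  if (one_based) raw$start_bp <- raw$start_bp - 1
  comparison_table(raw, label = label, annotation = annotation,
                   metadata = list(source = path))
}

#' Write a comparison table to tab-separated text
#'
#' @param table a [comparison_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_comparison_table <- function(table, path) {
  utils::write.table(table$genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a result table as deterministic tab-separated text
#'
#' Writes any tabular result with a header line, the given column and row
#' order, and floating-point values at a fixed precision (10 significant
#' digits) so repeated writes of the same records are byte-identical.
#'
#' @param records data.frame of results (may have zero rows).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (col in names(out)) {
    if (is.double(out[[col]]))
      out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                           sprintf("%.10g", out[[col]]))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
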