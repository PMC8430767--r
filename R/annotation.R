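# Genome annotation container: chromosome geometry plus structural tracks.
#
# Coordinate convention for the whole package: 0-based, half-open
# [start, end).  Readers can convert 1-based inputs via `one_based = TRUE`.

HUMAN_CHROMS <- c(paste0("chr", 1:22), "chrX", "chrY")

# Canonical chromosome ordering for the 1D concatenation of the genome:
# chr1..chr22, chrX, chrY; names outside this set keep their input order
# and are appended after the known ones.
order_chromosomes <- function(names) {
  known <- match(names, HUMAN_CHROMS)
  ord <- order(is.na(known), known, seq_along(names))
  names[ord]
}

#' Construct a genome annotation
#'
#' Bundles chromosome geometry (length and centromere position) with optional
#' structural tracks: Alu element positions, replication timing intervals
#' (timing index in \[-1, 1\], -1 late to +1 early), Giemsa cytoband
#' intervals, TAD and LAD intervals.  All intervals are 0-based half-open and
#' are clipped to chromosome bounds; intervals within one track must not
#' overlap on a chromosome.
#'
#' @param chromosomes data.frame with columns `name`, `length_bp` and
#'   optionally `centromere_bp` (default: mid-chromosome, flagged).
#' @param alu data.frame with columns `chrom`, `pos` (element start), or NULL.
#' @param replication data.frame `chrom`, `start`, `end`, `timing`, or NULL.
#' @param cytobands data.frame `chrom`, `start`, `end`, `stain`, or NULL.
#' @param tads data.frame `chrom`, `start`, `end` and optional `tad_id`.
#' @param lads data.frame `chrom`, `start`, `end` and optional `lad_id`.
#' @return object of class `genome_annotation`.
#' @export
genome_annotation <- function(chromosomes, alu = NULL, replication = NULL,
                              cytobands = NULL, tads = NULL, lads = NULL) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length_bp") %in% names(chromosomes)))
  chromosomes$name <- as.character(chromosomes$name)
  if (anyDuplicated(chromosomes$name))
    stop("duplicate chromosome names in sizes table")
  if (any(chromosomes$length_bp <= 0))
    stop("parameter error: zero or negative chromosome length")
  missing_tracks <- character(0)
  if (is.null(chromosomes$centromere_bp)) {
    chromosomes$centromere_bp <- floor(chromosomes$length_bp / 2)
    missing_tracks <- c(missing_tracks, "centromeres")
  }
  if (any(chromosomes$centromere_bp <= 0 |
          chromosomes$centromere_bp >= chromosomes$length_bp))
    stop("centromere position must lie strictly inside the chromosome")
  chromosomes <- chromosomes[match(order_chromosomes(chromosomes$name),
                                   chromosomes$name), , drop = FALSE]
  rownames(chromosomes) <- NULL
  lens <- stats::setNames(chromosomes$length_bp, chromosomes$name)

  clean_track <- function(df, what, value_col = NULL) {
    if (is.null(df) || nrow(df) == 0L) {
      missing_tracks <<- c(missing_tracks, what)
      out <- data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0))
      if (!is.null(value_col)) out[[value_col]] <- character(0)
      return(out)
    }
    keep <- df$chrom %in% names(lens)
    if (any(!keep))
      warning(sum(!keep), " ", what,
              " intervals on chromosomes absent from sizes were skipped")
    df <- df[keep, , drop = FALSE]
    if (any(df$end <= df$start))
      stop("format error: interval end <= start in ", what, " track")
    df$start <- pmax(0, df$start)
    df$end <- pmin(df$end, lens[df$chrom])
    df <- df[df$end > df$start, , drop = FALSE]
    df <- df[order(match(df$chrom, chromosomes$name), df$start), , drop = FALSE]
    sp <- split(seq_len(nrow(df)), df$chrom)
    for (idx in sp) {
      if (length(idx) > 1L &&
          any(df$start[idx][-1L] < df$end[idx][-length(idx)]))
        stop("overlapping intervals within ", what, " track")
    }
    rownames(df) <- NULL
    df
  }

  if (!is.null(alu) && nrow(alu)) {
    keep <- alu$chrom %in% names(lens) & alu$pos >= 0 & alu$pos < lens[alu$chrom]
    if (any(!keep)) warning(sum(!keep), " Alu positions outside the genome were skipped")
    alu <- alu[keep, , drop = FALSE]
    alu <- alu[order(match(alu$chrom, chromosomes$name), alu$pos), , drop = FALSE]
    rownames(alu) <- NULL
  } else {
    missing_tracks <- c(missing_tracks, "alu")
    alu <- data.frame(chrom = character(0), pos = numeric(0))
  }
  replication <- clean_track(replication, "replication", "timing")
  if (nrow(replication) && (!is.numeric(replication$timing) ||
                            any(abs(replication$timing) > 1)))
    stop("replication timing index must be numeric in [-1, 1]")
  cytobands <- clean_track(cytobands, "cytobands", "stain")
  tads <- clean_track(tads, "tads", "tad_id")
  if (nrow(tads) && is.null(tads$tad_id)) tads$tad_id <- paste0("tad", seq_len(nrow(tads)))
  lads <- clean_track(lads, "lads", "lad_id")
  if (nrow(lads) && is.null(lads$lad_id)) lads$lad_id <- paste0("lad", seq_len(nrow(lads)))

  structure(list(chromosomes = chromosomes, alu = alu,
                 replication = replication, cytobands = cytobands,
                 tads = tads, lads = lads,
                 missing_tracks = unique(missing_tracks)),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("Genome annotation:", nrow(x$chromosomes), "chromosomes,",
      format(sum(x$chromosomes$length_bp), big.mark = ","), "bp\n")
  cat("  tracks: alu(", nrow(x$alu), "), replication(", nrow(x$replication),
      "), cytobands(", nrow(x$cytobands), "), tads(", nrow(x$tads),
      "), lads(", nrow(x$lads), ")\n", sep = "")
  if (length(x$missing_tracks))
    cat("  absent tracks:", paste(x$missing_tracks, collapse = ", "), "\n")
  invisible(x)
}

chrom_lengths <- function(annotation) {
  stats::setNames(annotation$chromosomes$length_bp, annotation$chromosomes$name)
}

#' Read a genome annotation from delimited text tracks
#'
#' `paths` is a named list of file paths.  `sizes` (two-column TSV: name,
#' length) is mandatory; `centromeres` (two-column TSV: name, position) and
#' the BED-like tracks `alu`, `replication`, `cytobands`, `tads`, `lads`
#' (tab-separated chrom, start, end \[, value/label\], no header) are
#' optional.  Absent tracks yield empty tracks recorded in
#' `missing_tracks`.
#'
#' @param paths named list of file paths; `paths$sizes` required.
#' @param one_based logical; if TRUE interval starts are converted from
#'   1-based closed to 0-based half-open coordinates (start - 1).
#' @return a [genome_annotation()].
#' @export
read_genome_annotation <- function(paths, one_based = FALSE) {
  if (is.null(paths$sizes)) stop("format error: chromosome sizes file is mandatory")
  sizes <- utils::read.table(paths$sizes, sep = "\t", header = FALSE,
                             col.names = c("name", "length_bp"),
                             colClasses = c("character", "numeric"))
  chroms <- data.frame(name = sizes$name, length_bp = sizes$length_bp)
  if (!is.null(paths$centromeres)) {
    cen <- utils::read.table(paths$centromeres, sep = "\t", header = FALSE,
                             col.names = c("name", "pos"),
                             colClasses = c("character", "numeric"))
    chroms$centromere_bp <- cen$pos[match(chroms$name, cen$name)] -
      if (one_based) 1 else 0
  }
  read_bed <- function(path, value_name = NULL) {
    if (is.null(path)) return(NULL)
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    names(df)[1:3] <- c("chrom", "start", "end")
    if (one_based) df$start <- df$start - 1
    if (!is.null(value_name) && ncol(df) >= 4L) names(df)[4L] <- value_name
    df
  }
  alu <- NULL
  if (!is.null(paths$alu)) {
    bed <- read_bed(paths$alu)
    alu <- data.frame(chrom = bed$chrom, pos = bed$start)
  }
  genome_annotation(chroms,
                    alu = alu,
                    replication = read_bed(paths$replication, "timing"),
                    cytobands = read_bed(paths$cytobands, "stain"),
                    tads = read_bed(paths$tads, "tad_id"),
                    lads = read_bed(paths$lads, "lad_id"))
}

#' Write a genome annotation to a directory of delimited text tracks
#'
#' Inverse of [read_genome_annotation()]; writes `sizes.tsv`,
#' `centromeres.tsv` and one BED-like file per non-empty track.
#'
#' @param annotation a [genome_annotation()].
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_genome_annotation <- function(annotation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(sizes = file.path(dir, "sizes.tsv"),
                centromeres = file.path(dir, "centromeres.tsv"))
  utils::write.table(annotation$chromosomes[, c("name", "length_bp")],
                     paths$sizes, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(annotation$chromosomes[, c("name", "centromere_bp")],
                     paths$centromeres, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (nrow(annotation$alu)) {
    paths$alu <- file.path(dir, "alu.bed")
    bed <- data.frame(chrom = annotation$alu$chrom,
                      start = annotation$alu$pos,
                      end = annotation$alu$pos + 1)
    utils::write.table(bed, paths$alu, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  for (tr in c("replication", "cytobands", "tads", "lads")) {
    df <- annotation[[tr]]
    if (nrow(df)) {
      paths[[tr]] <- file.path(dir, paste0(tr, ".bed"))
      utils::write.table(df, paths[[tr]], sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(paths)
}
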