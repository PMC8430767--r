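# Synthetic-data generators.  They emulate the statistical structure the
# region analysis assumes: a weak uncorrelated fold-change background,
# strongly regulated gene pairs scattered over the genome, and co-regulated
# chromosomal regions with a shared fold-change sign.  All generators are
# pure functions of (parameters, seed).

#' Default synthetic genome for simulations
#'
#' Named vector of 24 chromosome lengths (bp) with the proportions of the
#' human karyotype.  The total span (about 1 Gb) is scaled to one third of
#' the physical assembly: gene placement in the generators is uniform,
#' without the strong gene-density clustering of the real genome, so the
#' span is chosen to reproduce a realistic number of genes per analysis
#' window instead of physical base pairs — at the default 16,800 genes this
#' gives roughly 160 genes per 10 Mb window, of which about 20 fall into a
#' top-2000 selection, matching the occupancy regime in which the binned
#' statistic operates on real data.
#'
#' @return named numeric vector of chromosome lengths in bp.
#' @export
default_genome <- function() {
  mb <- c(248, 242, 198, 190, 182, 171, 159, 145, 138, 134, 135, 133,
          114, 107, 102, 90, 83, 80, 59, 64, 47, 51, 156, 57)
  stats::setNames(round(mb * 1e6 / 3), c(paste0("chr", 1:22), "chrX", "chrY"))
}

#' Simulation parameters
#'
#' Collects the tunable parameters of the expression-table generators.
#' Defaults match the study conditions: 16,800 uniquely mapping genes, a
#' uniform background on \[-0.5, 0.5\] (Beta(1,1) mapped affinely), strong
#' pairs with |logFC| in \[1, 10\] differing by at most 0.1 between tables,
#' and region sites with half-widths in \[500 kb, 1.5 Mb\] (total spans of
#' 1-3 Mb).
#'
#' @param n_genes number of genes.
#' @param background_max_logfc half-width of the background logFC range.
#' @param beta_a,beta_b shape parameters of the background distribution
#'   before the affine map; (1, 1) is the uniform default.
#' @param n_strong_genes number of strongly regulated gene pairs (0-1000).
#' @param strong_logfc_range absolute logFC range of strong genes.
#' @param strong_pair_max_diff maximal absolute between-table difference.
#' @param n_sites number of co-regulated region sites (0-500).
#' @param site_halfwidth_range half-width range of a site in bp.
#' @param site_logfc_range absolute logFC range within sites.
#' @param seed mandatory integer seed.
#' @return object of class `simulation_spec` (a validated list).
#' @export
simulation_spec <- function(n_genes = 16800L,
                            background_max_logfc = 0.5,
                            beta_a = 1, beta_b = 1,
                            n_strong_genes = 0L,
                            strong_logfc_range = c(1, 10),
                            strong_pair_max_diff = 0.1,
                            n_sites = 0L,
                            site_halfwidth_range = c(500000, 1500000),
                            site_logfc_range = c(1, 10),
                            seed) {
  if (missing(seed) || is.null(seed)) stop("parameter error: seed is mandatory")
  if (n_genes <= 0) stop("parameter error: n_genes must be positive")
  if (n_strong_genes < 0 || n_strong_genes > n_genes)
    stop("parameter error: n_strong_genes must lie in [0, n_genes]")
  if (n_sites < 0) stop("parameter error: n_sites must be >= 0")
  stopifnot(background_max_logfc > 0, beta_a > 0, beta_b > 0,
            all(strong_logfc_range > 0), diff(strong_logfc_range) >= 0,
            strong_pair_max_diff > 0,
            all(site_halfwidth_range > 0), all(site_logfc_range > 0))
  structure(list(n_genes = as.integer(n_genes),
                 background_max_logfc = background_max_logfc,
                 beta_a = beta_a, beta_b = beta_b,
                 n_strong_genes = as.integer(n_strong_genes),
                 strong_logfc_range = strong_logfc_range,
                 strong_pair_max_diff = strong_pair_max_diff,
                 n_sites = as.integer(n_sites),
                 site_halfwidth_range = site_halfwidth_range,
                 site_logfc_range = site_logfc_range,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Generate a synthetic genome annotation
#'
#' Builds a deterministic (per seed) annotation with centromeres drawn
#' uniformly from the middle third of each chromosome, Poisson-placed Alu
#' positions, piecewise-constant replication timing in \[-1, 1\],
#' alternating gneg/gpos50 cytobands, tiling TAD intervals around 1 Mb, and
#' sparse LAD intervals with a target genome coverage.
#'
#' @param lengths_bp named vector of chromosome lengths; default
#'   [default_genome()].
#' @param seed integer seed.
#' @param alu_rate Alu elements per bp (default 3.5e-4, the human-scale
#'   average of roughly 35 elements per 100 kb).
#' @param lad_coverage target fraction of the genome covered by LADs.
#' @param tad_width_range TAD width range in bp.
#' @param replication_mean_bp mean replication-domain length.
#' @param cytoband_width_range cytoband width range in bp.
#' @return a [genome_annotation()].
#' @export
sim_annotation <- function(lengths_bp = default_genome(), seed,
                           alu_rate = 3.5e-4, lad_coverage = 0.2,
                           tad_width_range = c(5e5, 1.5e6),
                           replication_mean_bp = 1.5e6,
                           cytoband_width_range = c(1e6, 5e6)) {
  if (any(lengths_bp <= 0)) stop("parameter error: zero-length chromosome")
  if (is.null(names(lengths_bp)))
    names(lengths_bp) <- paste0("chr", seq_along(lengths_bp))
  with_seed(seed, {
    chroms <- data.frame(name = names(lengths_bp), length_bp = lengths_bp,
                         row.names = NULL)
    chroms$centromere_bp <- floor(stats::runif(nrow(chroms),
                                               lengths_bp / 3, 2 * lengths_bp / 3))
    alu <- NULL; repl <- NULL; cyto <- NULL; tads <- NULL; lads <- NULL
    # segment a chromosome into consecutive intervals with given width draws
    tile <- function(L, draw) {
      starts <- numeric(0); pos <- 0
      while (pos < L) { starts <- c(starts, pos); pos <- pos + draw() }
      ends <- c(starts[-1L], L)
      cbind(starts, pmin(ends, L))
    }
    for (i in seq_len(nrow(chroms))) {
      L <- chroms$length_bp[i]; nm <- chroms$name[i]
      if (alu_rate > 0) {
        n_alu <- stats::rpois(1L, L * alu_rate)
        if (n_alu > 0)
          alu <- rbind(alu, data.frame(chrom = nm,
                                       pos = sort(floor(stats::runif(n_alu, 0, L)))))
      }
      seg <- tile(L, function() stats::rexp(1L, 1 / replication_mean_bp) + 2e5)
      repl <- rbind(repl, data.frame(chrom = nm, start = seg[, 1L],
                                     end = seg[, 2L],
                                     timing = stats::runif(nrow(seg), -1, 1)))
      seg <- tile(L, function() stats::runif(1L, cytoband_width_range[1L],
                                             cytoband_width_range[2L]))
      cyto <- rbind(cyto, data.frame(chrom = nm, start = seg[, 1L],
                                     end = seg[, 2L],
                                     stain = rep_len(c("gneg", "gpos50"), nrow(seg))))
      seg <- tile(L, function() stats::runif(1L, tad_width_range[1L],
                                             tad_width_range[2L]))
      tads <- rbind(tads, data.frame(chrom = nm, start = seg[, 1L],
                                     end = seg[, 2L],
                                     tad_id = sprintf("%s_tad%04d", nm,
                                                      seq_len(nrow(seg)))))
      if (lad_coverage > 0) {
        lad_mean <- 7e5
        gap_mean <- lad_mean * (1 - lad_coverage) / lad_coverage
        s <- numeric(0); e <- numeric(0)
        pos <- stats::rexp(1L, 1 / gap_mean)
        while (pos < L) {
          w <- stats::rexp(1L, 1 / lad_mean) + 1e5
          s <- c(s, pos); e <- c(e, min(pos + w, L))
          pos <- pos + w + stats::rexp(1L, 1 / gap_mean) + 1e4
        }
        if (length(s))
          lads <- rbind(lads, data.frame(chrom = nm, start = s, end = e,
                                         lad_id = sprintf("%s_lad%04d", nm,
                                                          seq_along(s))))
      }
    }
    genome_annotation(chroms, alu = alu, replication = repl, cytobands = cyto,
                      tads = tads, lads = lads)
  })
}

# Rank-based plumbing p-values: monotone decreasing in |logFC|, marginally
# uniform on {1/n, ..., 1}.  Used only for weighting-free threshold
# operations downstream; the generators do not model a test statistic.
rank_pvalues <- function(logfc) {
  n <- length(logfc)
  (n + 1L - rank(abs(logfc), ties.method = "first")) / n
}

sim_one_table <- function(ids, chrom, pos, spec, label) {
  n <- length(ids)
  logfc <- (stats::rbeta(n, spec$beta_a, spec$beta_b) - 0.5) *
    2 * spec$background_max_logfc
  avg_expr <- stats::rlnorm(n, 0, 1)
  data.frame(gene_id = ids, chromosome = chrom, start_bp = pos,
             logfc = logfc, avg_expr = avg_expr,
             p_value = rank_pvalues(logfc))
}

#' Generate a pair of background-only comparison tables
#'
#' Places `n_genes` genes on the annotation (chromosome drawn proportional
#' to length, position uniform) and assigns each table independent logFC
#' values from the affinely mapped Beta background, so the pipeline Spearman
#' correlation between the two tables is 0 on average.  Average expression is
#' lognormal(0, 1); p-values are rank-based in |logFC| (documented plumbing).
#'
#' @param annotation a [genome_annotation()].
#' @param spec a [simulation_spec()].
#' @return list of two [comparison_table()]s (`a`, `b`) over identical genes
#'   and positions.
#' @export
sim_background_pair <- function(annotation, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  lens <- chrom_lengths(annotation)
  with_seed(spec$seed, {
    n <- spec$n_genes
    ids <- sprintf("g%06d", seq_len(n))
    chrom <- sample(names(lens), n, replace = TRUE, prob = lens / sum(lens))
    pos <- floor(stats::runif(n, 0, lens[chrom]))
    ta <- sim_one_table(ids, chrom, pos, spec, "a")
    tb <- sim_one_table(ids, chrom, pos, spec, "b")
    list(a = comparison_table(ta, label = "sim_a", annotation = annotation),
         b = comparison_table(tb, label = "sim_b", annotation = annotation))
  })
}

refresh_pvalues <- function(tab) {
  tab$genes$p_value <- rank_pvalues(tab$genes$logfc)
  tab
}

#' Plant strongly regulated gene pairs into a table pair
#'
#' Chooses `n_strong_genes` genes uniformly without replacement and assigns
#' each an absolute logFC in the strong range with a common sign in both
#' tables and an absolute between-table difference of at most
#' `strong_pair_max_diff`.  Positions are untouched, so the strong pairs are
#' scattered over the whole genome; gene-level pairing, not co-location,
#' carries the induced correlation.
#'
#' @param pair list of two [comparison_table()]s as from
#'   [sim_background_pair()].
#' @param spec a [simulation_spec()] with `n_strong_genes` set.
#' @return the modified table pair.
#' @export
plant_strong_pairs <- function(pair, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  k <- spec$n_strong_genes
  if (k > nrow(pair$a$genes))
    stop("parameter error: n_strong_genes exceeds the table size")
  if (k == 0L) return(pair)
  with_seed(derive_seed(spec$seed, "strong"), {
    idx <- sample.int(nrow(pair$a$genes), k)
    sgn <- sample(c(-1, 1), k, replace = TRUE)
    lo <- spec$strong_logfc_range[1L]; hi <- spec$strong_logfc_range[2L]
    mag_a <- stats::runif(k, lo, hi)
    mag_b <- pmin(pmax(mag_a + stats::runif(k, -spec$strong_pair_max_diff,
                                            spec$strong_pair_max_diff),
                       lo), hi)
    pair$a$genes$logfc[idx] <- sgn * mag_a
    pair$b$genes$logfc[match(pair$a$genes$gene_id[idx],
                             pair$b$genes$gene_id)] <- sgn * mag_b
    list(a = refresh_pvalues(pair$a), b = refresh_pvalues(pair$b))
  })
}

#' Plant co-regulated chromosomal region sites into a table pair
#'
#' Draws `n_sites` center genes uniformly; per site a half-width in the
#' configured range defines a region on the center's chromosome, and every
#' gene within it receives an absolute logFC in the site range with a sign
#' that is constant within the site and shared between the two tables.  Only
#' location, extent and sign are shared: per-table gene magnitudes are
#' independent draws.  Overlapping sites are permitted; later sites
#' overwrite earlier assignments, and the returned region list reports drawn
#' extents (clipped to chromosome bounds), not merged ones.
#'
#' @param pair list of two [comparison_table()]s.
#' @param annotation the [genome_annotation()] the pair was generated on.
#' @param spec a [simulation_spec()] with `n_sites` set.
#' @return list with elements `tables` (the modified pair) and `regions`
#'   (data.frame chrom, start, end, sign).
#' @export
plant_grcr_sites <- function(pair, annotation, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n_sites <- spec$n_sites
  if (n_sites < 0L) stop("parameter error: n_sites must be >= 0")
  if (n_sites == 0L)
    return(list(tables = pair,
                regions = data.frame(chrom = character(0), start = numeric(0),
                                     end = numeric(0), sign = numeric(0))))
  lens <- chrom_lengths(annotation)
  ga <- pair$a$genes; gb <- pair$b$genes
  b_of_a <- match(ga$gene_id, gb$gene_id)
  with_seed(derive_seed(spec$seed, "sites"), {
    centers <- sample.int(nrow(ga), n_sites, replace = TRUE)
    hw <- stats::runif(n_sites, spec$site_halfwidth_range[1L],
                       spec$site_halfwidth_range[2L])
    sgn <- sample(c(-1, 1), n_sites, replace = TRUE)
    lo <- spec$site_logfc_range[1L]; hi <- spec$site_logfc_range[2L]
    regions <- data.frame(chrom = character(n_sites), start = numeric(n_sites),
                          end = numeric(n_sites), sign = sgn)
    for (s in seq_len(n_sites)) {
      ci <- centers[s]
      chrom <- ga$chromosome[ci]; cpos <- ga$start_bp[ci]
      in_site <- which(ga$chromosome == chrom &
                         abs(ga$start_bp - cpos) <= hw[s])
      m <- length(in_site)
      ga$logfc[in_site] <- sgn[s] * stats::runif(m, lo, hi)
      gb$logfc[b_of_a[in_site]] <- sgn[s] * stats::runif(m, lo, hi)
      regions$chrom[s] <- chrom
      # half-open extent; integer gene positions never sit exactly at the
      # continuous boundary cpos + hw, so the span stays within 2*hw
      regions$start[s] <- max(0, cpos - hw[s])
      regions$end[s] <- min(lens[[chrom]], cpos + hw[s])
    }
    pair$a$genes <- ga; pair$b$genes <- gb
    list(tables = list(a = refresh_pvalues(pair$a),
                       b = refresh_pvalues(pair$b)),
         regions = regions)
  })
}

#' Generate a differential Hi-C bin-pair table
#'
#' Emulates the output of an upstream differential interaction test on 1 Mb
#' bins: all intrachromosomal pairs carry a distance-decaying positive
#' abundance, a sampled set of interchromosomal pairs carries near-zero
#' abundance, p-values are uniform under the null, and an optional set of
#' pairs anchored inside `enriched_regions` receives small p-values and
#' positive logFC.
#'
#' @param annotation a [genome_annotation()].
#' @param enriched_regions data.frame (chrom, start, end) of regions to
#'   plant differential interactions into, or NULL.
#' @param n_planted number of planted differential intra pairs.
#' @param bin_bp bin size in bp (default 1e6).
#' @param n_inter number of sampled interchromosomal pairs.
#' @param planted_p_max upper bound of planted p-values.
#' @param decay_bp distance-decay constant of intra abundance.
#' @param seed integer seed.
#' @return object of class `hic_bin_pairs` (see [hic_bin_pairs()]).
#' @export
sim_hic_table <- function(annotation, enriched_regions = NULL, n_planted = 0L,
                          bin_bp = 1e6, n_inter = 2000L,
                          planted_p_max = 1e-8, decay_bp = 1e7, seed) {
  lens <- chrom_lengths(annotation)
  if (!length(lens)) stop("parameter error: empty genome")
  n_bins <- pmax(1L, as.integer(ceiling(lens / bin_bp)))
  with_seed(seed, {
    pairs <- NULL
    for (ci in seq_along(lens)) {
      nb <- n_bins[ci]
      idx <- which(upper.tri(matrix(0, nb, nb), diag = TRUE), arr.ind = TRUE)
      d <- (idx[, 2L] - idx[, 1L]) * bin_bp
      pairs <- rbind(pairs, data.frame(
        chrom_a = names(lens)[ci], bin_start_a = (idx[, 1L] - 1) * bin_bp,
        chrom_b = names(lens)[ci], bin_start_b = (idx[, 2L] - 1) * bin_bp,
        abundance = 10 * exp(-d / decay_bp) *
          stats::rlnorm(nrow(idx), 0, 0.3) + 1e-3))
    }
    if (n_inter > 0L && length(lens) > 1L) {
      ca <- sample(names(lens), n_inter, replace = TRUE,
                   prob = n_bins / sum(n_bins))
      cb <- sample(names(lens), n_inter, replace = TRUE,
                   prob = n_bins / sum(n_bins))
      ok <- ca != cb
      ca <- ca[ok]; cb <- cb[ok]
      swap <- match(ca, names(lens)) > match(cb, names(lens))
      tmp <- ca[swap]; ca[swap] <- cb[swap]; cb[swap] <- tmp
      ia <- floor(stats::runif(length(ca), 0, n_bins[match(ca, names(lens))]))
      ib <- floor(stats::runif(length(cb), 0, n_bins[match(cb, names(lens))]))
      inter <- data.frame(chrom_a = ca, bin_start_a = ia * bin_bp,
                          chrom_b = cb, bin_start_b = ib * bin_bp,
                          abundance = abs(stats::rnorm(length(ca), 0, 0.05)))
      inter <- inter[!duplicated(inter[, 1:4]), , drop = FALSE]
      pairs <- rbind(pairs, inter)
    }
    pairs$logfc <- stats::rnorm(nrow(pairs), 0, 0.5)
    pairs$p_value <- stats::runif(nrow(pairs))
    if (n_planted > 0L) {
      if (is.null(enriched_regions) || nrow(enriched_regions) == 0L)
        stop("parameter error: n_planted > 0 requires enriched_regions")
      bin_in_region <- function(chrom, start) {
        hit <- rep(FALSE, length(chrom))
        for (r in seq_len(nrow(enriched_regions))) {
          hit <- hit | (chrom == enriched_regions$chrom[r] &
                          start < enriched_regions$end[r] &
                          start + bin_bp > enriched_regions$start[r])
        }
        hit
      }
      cand <- which(pairs$chrom_a == pairs$chrom_b &
                      (bin_in_region(pairs$chrom_a, pairs$bin_start_a) |
                         bin_in_region(pairs$chrom_b, pairs$bin_start_b)))
      if (length(cand) == 0L) stop("no intra pairs anchored in enriched_regions")
      sel <- if (length(cand) <= n_planted) cand else sample(cand, n_planted)
      pairs$p_value[sel] <- stats::runif(length(sel), 0, planted_p_max)
      pairs$logfc[sel] <- stats::runif(length(sel), 1, 3)
    }
    hic_bin_pairs(pairs, bin_bp = bin_bp, annotation = annotation)
  })
}

#' Sweep a simulation model through the full region pipeline
#'
#' For each grid value of the model's strength parameter (number of strong
#' gene pairs or number of region sites), generates `reps` independent table
#' pairs, runs top-N selection, binning and Spearman correlation to obtain
#' the actual coefficient, and a location-permutation null to obtain the
#' expected coefficient; reports per-grid-point means and moving-average
#' smoothed curves (window 30 over the grid order).
#'
#' @param annotation a [genome_annotation()].
#' @param model `"strong_genes"` (grid = numbers of strong pairs, 0-1000) or
#'   `"grcr_sites"` (grid = numbers of region sites, 0-500).
#' @param grid integer vector of model strengths.
#' @param reps simulations per grid point (default 100).
#' @param seed integer master seed.
#' @param n_genes genes per simulated table.
#' @param null_reps permutations per null (default 100).
#' @param top_n,step_bp,window_bp,min_genes pipeline parameters, see
#'   [bin_trace()].
#' @param smooth_window moving-average window over the grid order.
#' @return data.frame with columns `n`, `mean_actual_rho`,
#'   `mean_expected_rho`, `smooth_actual_rho`, `smooth_expected_rho`.
#' @export
sweep_models <- function(annotation, model = c("strong_genes", "grcr_sites"),
                         grid, reps = 100L, seed, n_genes = 16800L,
                         null_reps = 100L, top_n = 2000L, step_bp = 5e6,
                         window_bp = 1e7, min_genes = 10L,
                         smooth_window = 30L) {
  model <- match.arg(model)
  if (reps <= 0L) stop("parameter error: reps must be positive")
  max_n <- if (model == "strong_genes") 1000L else 500L
  if (any(grid < 0L | grid > max_n))
    stop("parameter error: grid values outside the model's allowed range")
  mean_act <- mean_exp <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    act <- expct <- numeric(reps)
    for (r in seq_len(reps)) {
      sd_ <- derive_seed(seed, paste0(model, "_", grid[gi], "_", r))
      spec <- simulation_spec(n_genes = n_genes,
                              n_strong_genes = if (model == "strong_genes") grid[gi] else 0L,
                              n_sites = if (model == "grcr_sites") grid[gi] else 0L,
                              seed = sd_)
      pair <- sim_background_pair(annotation, spec)
      pair <- if (model == "strong_genes") plant_strong_pairs(pair, spec)
      else plant_grcr_sites(pair, annotation, spec)$tables
      ta <- bin_trace(select_top_n(pair$a, top_n), annotation, step_bp,
                      window_bp, min_genes)
      tb <- bin_trace(select_top_n(pair$b, top_n), annotation, step_bp,
                      window_bp, min_genes)
      cr <- spearman_correlate(ta, tb)
      act[r] <- if (is.na(cr$rho)) NA_real_ else cr$rho
      nul <- shuffle_null(pair$a, pair$b, annotation, reps = null_reps,
                          seed = derive_seed(sd_, "null"), top_n = top_n,
                          step_bp = step_bp, window_bp = window_bp,
                          min_genes = min_genes)
      expct[r] <- nul$rho_mean
    }
    mean_act[gi] <- mean(act, na.rm = TRUE)
    mean_exp[gi] <- mean(expct, na.rm = TRUE)
  }
  o <- order(grid)
  data.frame(n = grid,
             mean_actual_rho = mean_act,
             mean_expected_rho = mean_exp,
             smooth_actual_rho = moving_average(mean_act[o], smooth_window)[order(o)],
             smooth_expected_rho = moving_average(mean_exp[o], smooth_window)[order(o)])
}
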