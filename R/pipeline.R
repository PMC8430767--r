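# Orchestration: one configured run through the analysis graph, with
# deterministic per-stage seeding and a machine-readable manifest.

#' Run a configured analysis pipeline
#'
#' Executes the enabled stages in dependency order — simulate/read inputs,
#' region comparison (selection, binning, correlation, permutation null,
#' score), feature subsets, structural linear models, per-chromosome DEG
#' pinpointing, Hi-C overlap — and writes deterministic TSV outputs plus a
#' JSON manifest holding every parameter, per-stage seed, output checksum
#' and warning.  Per-stage seeds are derived from `master_seed` by a stable
#' hash of the stage name, so a partial re-run reproduces the numbers of a
#' full run.  Running the same configuration twice yields byte-identical
#' numeric outputs.
#'
#' @param config a named list, or the path to a YAML file holding one.
#'   Recognised keys:
#'   \describe{
#'     \item{output_dir}{output directory (required).}
#'     \item{master_seed}{integer; required when any stochastic stage is
#'       enabled.}
#'     \item{simulate}{list(`n_genes`, `model` in
#'       "background"/"strong"/"grcr", `n` strength, optional
#'       `chromosomes` named length vector) — or absent when `inputs` is
#'       given.}
#'     \item{inputs}{list(`table_a`, `table_b`, `annotation` dir,
#'       optional `hic`) of file paths.}
#'     \item{stages}{character vector out of "correlate", "subsets",
#'       "models", "pinpoint", "hic_overlap" (default: "correlate").}
#'     \item{params}{overrides: `top_n`, `step_bp`, `window_bp`,
#'       `min_genes`, `reps`, `model_reps`, `subset_features`, `model_ids`,
#'       `intra_fdr`, `inter_fdr`.}
#'   }
#' @return the manifest (named list), invisibly; also written as
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$output_dir)) stop("parameter error: output_dir required")
  stages <- setdiff(config$stages %||% "correlate", "none")
  if (!is.null(config$simulate) && !is.null(config$inputs))
    stop("parameter error: exactly one of simulate/inputs per dataset slot")
  stochastic <- length(stages) > 0L || !is.null(config$simulate)
  if (stochastic && is.null(config$master_seed))
    stop("parameter error: master_seed is mandatory when stochastic stages ",
         "are enabled")
  ms <- config$master_seed %||% 0L
  p <- config$params %||% list()
  top_n <- p$top_n %||% 2000L
  step_bp <- p$step_bp %||% 5e6
  window_bp <- p$window_bp %||% 1e7
  min_genes <- p$min_genes %||% 10L
  reps <- p$reps %||% 1000L

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "grcr",
                   version = as.character(utils::packageVersion("grcr")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   config = config, seeds = list(), outputs = list(),
                   warnings = character(0), completed_stages = character(0))
  emit <- function(df, name) {
    path <- file.path(config$output_dir, name)
    write_report_table(df, path)
    manifest$outputs[[name]] <<- list(path = path,
                                      md5 = unname(tools::md5sum(path)))
    path
  }
  finish <- function(status) {
    manifest$status <- status
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                         digits = NA)
    invisible(manifest)
  }

  ann <- NULL; pair <- NULL; regions <- NULL
  res <- tryCatch({
    if (length(stages) == 0L) {
      # nothing to run: record the validated configuration only
    } else if (!is.null(config$simulate)) {
      s <- config$simulate
      seed_ann <- derive_seed(ms, "annotation")
      seed_tab <- derive_seed(ms, "tables")
      manifest$seeds$annotation <- seed_ann
      manifest$seeds$tables <- seed_tab
      lengths_bp <- if (!is.null(s$chromosomes)) unlist(s$chromosomes) else
        default_genome()
      ann <- sim_annotation(lengths_bp = lengths_bp, seed = seed_ann)
      spec <- simulation_spec(
        n_genes = s$n_genes %||% 16800L,
        n_strong_genes = if (identical(s$model, "strong")) s$n %||% 0L else 0L,
        n_sites = if (identical(s$model, "grcr")) s$n %||% 0L else 0L,
        seed = seed_tab)
      pair <- sim_background_pair(ann, spec)
      if (identical(s$model, "strong")) {
        pair <- plant_strong_pairs(pair, spec)
      } else if (identical(s$model, "grcr")) {
        planted <- plant_grcr_sites(pair, ann, spec)
        pair <- planted$tables
        regions <- planted$regions
        emit(planted$regions, "planted_regions.tsv")
      }
      emit(pair$a$genes, "table_a.tsv")
      emit(pair$b$genes, "table_b.tsv")
      write_genome_annotation(ann, file.path(config$output_dir, "annotation"))
    } else if (!is.null(config$inputs)) {
      ann <- read_genome_annotation(as.list(
        stats::setNames(file.path(config$inputs$annotation,
                                  c("sizes.tsv", "centromeres.tsv")),
                        c("sizes", "centromeres"))))
      tracks <- c("alu.bed", "replication.bed", "cytobands.bed", "tads.bed",
                  "lads.bed")
      have <- file.exists(file.path(config$inputs$annotation, tracks))
      if (any(have)) {
        paths <- as.list(stats::setNames(
          file.path(config$inputs$annotation, tracks[have]),
          sub("\\..*$", "", tracks[have])))
        paths$sizes <- file.path(config$inputs$annotation, "sizes.tsv")
        if (file.exists(file.path(config$inputs$annotation, "centromeres.tsv")))
          paths$centromeres <- file.path(config$inputs$annotation,
                                         "centromeres.tsv")
        ann <- read_genome_annotation(paths)
      }
      pair <- list(a = read_comparison_table(config$inputs$table_a, ann,
                                             label = "a"),
                   b = read_comparison_table(config$inputs$table_b, ann,
                                             label = "b"))
    }

    fit <- NULL
    if ("correlate" %in% stages) {
      seed_cor <- derive_seed(ms, "correlate")
      manifest$seeds$correlate <- seed_cor
      fit <- grcr_compare(pair$a, pair$b, ann, top_n = top_n,
                          step_bp = step_bp, window_bp = window_bp,
                          min_genes = min_genes, reps = reps, seed = seed_cor)
      emit(summary(fit), "correlation.tsv")
      emit(fit$bins, "region_bins.tsv")
      manifest$completed_stages <- c(manifest$completed_stages, "correlate")
    }

    features <- NULL
    need_features <- any(c("subsets", "models") %in% stages)
    if (need_features) features <- annotate_features(pair$a, ann)

    if ("subsets" %in% stages) {
      feats <- p$subset_features %||% c("chrom_class", "arm_region",
                                        "alu_rich", "replication",
                                        "cytoband_sign")
      rows <- lapply(feats, function(fe) {
        res <- subset_grcr_analysis(pair$a, pair$b, features, fe, ann,
                                    seed = derive_seed(ms, paste0("subset_", fe)),
                                    top_n = top_n, step_bp = step_bp,
                                    window_bp = window_bp, reps = reps)
        one <- function(x, cls) {
          if (inherits(x, "grcr"))
            cbind(feature = fe, subset = cls, summary(x))
          else data.frame(feature = fe, subset = cls, rho_actual = NA_real_)
        }
        rbind_fill(one(res$high, "high"), one(res$low, "low"))
      })
      emit(do.call(rbind_fill, rows), "subsets.tsv")
      manifest$completed_stages <- c(manifest$completed_stages, "subsets")
    }

    if ("models" %in% stages) {
      ids <- p$model_ids %||% MODEL_IDS
      model_reps <- p$model_reps %||% 1000L
      rows <- lapply(ids, function(id) {
        f <- fit_bootstrap(build_design(id, pair$a, features, ann),
                           reps = model_reps,
                           seed = derive_seed(ms, paste0("model_", id)))
        if (id == "chrom_length")
          emit(chromosome_coefficients(f), "chromosome_coefficients.tsv")
        data.frame(model_id = id, mean_r2 = f$mean_r2, sem_r2 = f$sem_r2,
                   n_columns = length(f$coefficients), reps = f$reps)
      })
      emit(do.call(rbind, rows), "model_r2.tsv")
      manifest$completed_stages <- c(manifest$completed_stages, "models")
    }

    if ("pinpoint" %in% stages) {
      emit(cbind(table = "a", pinpoint_deg(pair$a)), "pinpoint_a.tsv")
      emit(cbind(table = "b", pinpoint_deg(pair$b)), "pinpoint_b.tsv")
      manifest$completed_stages <- c(manifest$completed_stages, "pinpoint")
    }

    if ("hic_overlap" %in% stages) {
      hic <- if (!is.null(config$inputs$hic)) {
        read_hic_table(config$inputs$hic, ann)
      } else {
        seed_hic <- derive_seed(ms, "hic")
        manifest$seeds$hic <- seed_hic
        sim_hic_table(ann, enriched_regions = regions,
                      n_planted = if (is.null(regions)) 0L else
                        p$hic_planted %||% 30L,
                      seed = seed_hic)
      }
      sig <- classify_and_filter(hic, intra_fdr = p$intra_fdr %||% 0.1,
                                 inter_fdr = p$inter_fdr %||% 0.2)
      emit(stratify_counts(sig, ann), "hic_stratified.tsv")
      if (!is.null(fit)) {
        ov <- overlap_fisher(sig, fit$bins, ann, bin_bp = hic$bin_bp)
        ct <- ov$contingency %||% matrix(NA_integer_, 2L, 2L)
        emit(data.frame(sig_in = ct[1, 1], sig_out = ct[1, 2],
                        rest_in = ct[2, 1], rest_out = ct[2, 2],
                        odds_ratio = ov$odds_ratio,
                        fisher_p = ov$fisher_p,
                        sidedness = ov$sidedness), "hic_overlap.tsv")
      }
      manifest$completed_stages <- c(manifest$completed_stages, "hic_overlap")
    }
    TRUE
  }, error = function(e) e)

  if (inherits(res, "error")) {
    manifest$warnings <- c(manifest$warnings,
                           paste("stage failure:", conditionMessage(res)))
    finish("partial")
    stop("pipeline failed after stages [",
         paste(manifest$completed_stages, collapse = ", "), "]: ",
         conditionMessage(res))
  }
  finish("complete")
}

# rbind data.frames with possibly different column sets (missing -> NA)
rbind_fill <- function(...) {
  dfs <- Filter(Negate(is.null), list(...))
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (cn in setdiff(cols, names(d))) d[[cn]] <- NA
    d[, cols, drop = FALSE]
  }))
}
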