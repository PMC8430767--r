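# Structural linear models of per-gene logFC, elastic-net fitting with
# bootstrapped 90:10 held-out evaluation, per-chromosome coefficient
# extraction, and per-chromosome DEG pinpointing.

MODEL_IDS <- c("chrom_length", "chrom_ends", "alu", "replication",
               "lads", "tads", "cytobands", "ends_length",
               "ends_length_alu_rep")

# all degree-<=2 monomials of the columns of X, including the constant:
# 1, x_j, x_j^2, x_j x_k  ->  choose(p + 2, 2) columns for p inputs
poly2_expand <- function(X) {
  p <- ncol(X)
  cols <- list(`(const)` = rep(1, nrow(X)))
  for (j in seq_len(p)) cols[[colnames(X)[j]]] <- X[, j]
  for (j in seq_len(p)) cols[[paste0(colnames(X)[j], "^2")]] <- X[, j]^2
  if (p > 1L) {
    for (j in seq_len(p - 1L)) for (k in (j + 1L):p) {
      cols[[paste0(colnames(X)[j], ":", colnames(X)[k])]] <- X[, j] * X[, k]
    }
  }
  do.call(cbind, cols)
}

indicator_matrix <- function(values, levels) {
  X <- matrix(0, length(values), length(levels),
              dimnames = list(NULL, levels))
  hit <- !is.na(values) & values %in% levels
  X[cbind(which(hit), match(values[hit], levels))] <- 1
  X
}

#' Build the design matrix of a structural linear model
#'
#' The response is the per-gene logFC; the predictors encode one chromatin
#' structure hypothesis:
#' \describe{
#'   \item{chrom_length}{one 0/1 indicator per annotation chromosome
#'     (24 columns on a full human-style genome).}
#'   \item{chrom_ends}{indicators for p-arm end, q-arm end, interior
#'     (3 columns).}
#'   \item{alu}{the single numeric Alu count column.}
#'   \item{replication}{the single replication timing index column.}
#'   \item{lads, tads}{one indicator per domain occupied by at least one
#'     gene plus a no-domain indicator.}
#'   \item{cytobands}{one indicator per occupied cytoband (no outside
#'     column; cytobands tile the chromosomes).}
#'   \item{ends_length}{full degree-2 monomial expansion (constant, linear,
#'     squares, pairwise products) of the 24 + 3 indicator columns:
#'     choose(29, 2) = 406 columns.}
#'   \item{ends_length_alu_rep}{the same expansion of the 29 base columns
#'     including Alu count and replication index: choose(31, 2) = 465
#'     columns.}
#' }
#' Genes with an undefined value in a required feature are dropped with the
#' count recorded.
#'
#' @param model_id one of the ids above.
#' @param table a [comparison_table()] providing the response.
#' @param features [annotate_features()] output for the table's genes
#'   (not needed for `chrom_length`).
#' @param annotation a [genome_annotation()] (needed for `chrom_length` and
#'   the combined models' chromosome column set).
#' @return object of class `grcr_design`: `model_id`, matrix `X`, response
#'   `y`, `gene_id`, `column_names`, `n_dropped`.
#' @export
build_design <- function(model_id, table, features = NULL, annotation = NULL) {
  if (!model_id %in% MODEL_IDS)
    stop("parameter error: unknown model_id '", model_id, "'")
  g <- table$genes
  f <- if (!is.null(features))
    features[match(g$gene_id, features$gene_id), , drop = FALSE] else NULL
  need_feature <- function(col, track) {
    if (is.null(f) || all(is.na(f[[col]])))
      stop("feature error: model '", model_id, "' requires the ", track,
           " track")
    f[[col]]
  }
  chrom_cols <- function() {
    if (is.null(annotation))
      stop("parameter error: model '", model_id, "' requires the annotation")
    indicator_matrix(g$chromosome, annotation$chromosomes$name)
  }
  arm_cols <- function() {
    arm <- need_feature("arm_region", "chromosome geometry")
    indicator_matrix(arm, c("p_end", "q_end", "interior"))
  }
  keep <- rep(TRUE, nrow(g))
  X <- switch(model_id,
    chrom_length = chrom_cols(),
    chrom_ends = arm_cols(),
    alu = {
      v <- need_feature("alu_count", "Alu")
      keep <- !is.na(v)
      matrix(as.numeric(v), ncol = 1L, dimnames = list(NULL, "alu_count"))
    },
    replication = {
      v <- need_feature("rep_index", "replication")
      keep <- !is.na(v)
      matrix(v, ncol = 1L, dimnames = list(NULL, "rep_index"))
    },
    lads = {
      v <- need_feature("lad_id", "LAD")
      occupied <- sort(unique(v[!is.na(v)]))
      cbind(indicator_matrix(v, occupied),
            no_LAD = as.numeric(is.na(v)))
    },
    tads = {
      v <- need_feature("tad_id", "TAD")
      occupied <- sort(unique(v[!is.na(v)]))
      cbind(indicator_matrix(v, occupied),
            no_TAD = as.numeric(is.na(v)))
    },
    cytobands = {
      v <- need_feature("cytoband_id", "cytoband")
      keep <- !is.na(v)
      indicator_matrix(v, sort(unique(v[!is.na(v)])))
    },
    ends_length = poly2_expand(cbind(chrom_cols(), arm_cols())),
    ends_length_alu_rep = {
      alu <- need_feature("alu_count", "Alu")
      rep_ <- need_feature("rep_index", "replication")
      keep <- !is.na(alu) & !is.na(rep_)
      poly2_expand(cbind(chrom_cols(), arm_cols(),
                         alu_count = as.numeric(alu), rep_index = rep_))
    })
  X <- X[keep, , drop = FALSE]
  structure(list(model_id = model_id, X = X, y = g$logfc[keep],
                 gene_id = g$gene_id[keep], column_names = colnames(X),
                 n_dropped = sum(!keep)),
            class = "grcr_design")
}

#' @export
print.grcr_design <- function(x, ...) {
  cat("Design '", x$model_id, "': ", nrow(x$X), " genes x ", ncol(x$X),
      " columns", if (x$n_dropped) paste0(" (", x$n_dropped, " dropped)"),
      "\n", sep = "")
  invisible(x)
}

#' Fit a structural model by bootstrapped elastic net
#'
#' Per repetition, the rows (ordered by gene id, so the split sequence is
#' invariant to input row order) are split at random into 90% training and
#' 10% held-out data; an l1+l2-penalised linear model is fitted on the
#' training part and the coefficient of determination R^2 = 1 - SSE/SST is
#' computed on the held-out part (negative values allowed).  Mean R^2, its
#' standard error, and the coefficient means over repetitions are reported.
#'
#' @param design a [build_design()] result.
#' @param reps bootstrap repetitions (default 1000).
#' @param train_fraction training fraction of the split (default 0.9).
#' @param seed integer seed.
#' @param lambda elastic-net penalty strength (default 0.01: light
#'   regularisation well below the scale of fold-change effects).
#' @param alpha l1:l2 mixing (default 0.5).
#' @param standardize standardize predictors inside the fit (coefficients
#'   are reported on the original scale).
#' @return object of class `enet_fit`: `model_id`, `mean_r2`, `sem_r2`,
#'   `coefficients` (named means), `reps`, `n_failed`, `seed`, `penalty`.
#' @export
fit_bootstrap <- function(design, reps = 1000L, train_fraction = 0.9, seed,
                          lambda = 0.01, alpha = 0.5, standardize = TRUE) {
  stopifnot(inherits(design, "grcr_design"))
  n <- nrow(design$X)
  if (n < 20L) stop("parameter error: design must have at least 20 rows")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("parameter error: train_fraction must lie in (0, 1)")
  o <- order(design$gene_id)
  X <- design$X[o, , drop = FALSE]
  y <- design$y[o]
  if (stats::sd(y) == 0)
    return(structure(list(model_id = design$model_id, mean_r2 = NA_real_,
                          sem_r2 = NA_real_,
                          coefficients = stats::setNames(
                            rep(NA_real_, ncol(X)), colnames(X)),
                          reps = as.integer(reps), n_failed = as.integer(reps),
                          seed = seed, reason = "constant response",
                          penalty = list(lambda = lambda, alpha = alpha)),
                     class = "enet_fit"))
  # glmnet needs >= 2 predictors; pad single-column designs with a zero
  # column whose coefficient is discarded
  padded <- ncol(X) < 2L
  if (padded) X <- cbind(X, .pad = 0)
  n_train <- max(1L, floor(train_fraction * n))
  r2 <- rep(NA_real_, reps)
  coef_sum <- numeric(ncol(X))
  n_failed <- 0L
  with_seed(seed, {
    for (r in seq_len(reps)) {
      train <- sample.int(n, n_train)
      res <- tryCatch({
        fit <- glmnet::glmnet(X[train, , drop = FALSE], y[train],
                              alpha = alpha, lambda = lambda,
                              intercept = FALSE, standardize = standardize)
        beta <- as.numeric(fit$beta[, 1L])
        test <- setdiff(seq_len(n), train)
        pred <- as.numeric(X[test, , drop = FALSE] %*% beta)
        sst <- sum((y[test] - mean(y[test]))^2)
        if (sst == 0) NULL else list(r2 = 1 - sum((y[test] - pred)^2) / sst,
                                     beta = beta)
      }, error = function(e) NULL)
      if (is.null(res)) { n_failed <- n_failed + 1L; next }
      r2[r] <- res$r2
      coef_sum <- coef_sum + res$beta
    }
  })
  n_ok <- reps - n_failed
  if (n_failed > 0.01 * reps)
    warning("fit flagged invalid: ", n_failed, " of ", reps,
            " repetitions failed")
  coefs <- stats::setNames(coef_sum / max(n_ok, 1L), colnames(X))
  if (padded) coefs <- coefs[names(coefs) != ".pad"]
  structure(list(model_id = design$model_id,
                 mean_r2 = mean(r2, na.rm = TRUE),
                 sem_r2 = stats::sd(r2, na.rm = TRUE) / sqrt(max(n_ok, 1L)),
                 coefficients = coefs, reps = as.integer(reps),
                 n_failed = n_failed, seed = seed,
                 penalty = list(lambda = lambda, alpha = alpha,
                                standardize = standardize,
                                train_fraction = train_fraction)),
            class = "enet_fit")
}

#' @export
print.enet_fit <- function(x, ...) {
  cat(sprintf("Elastic-net fit '%s': mean held-out R2 = %.4f (SEM %.2g, %d reps",
              x$model_id, x$mean_r2, x$sem_r2, x$reps))
  if (x$n_failed) cat(",", x$n_failed, "failed")
  cat(")\n")
  invisible(x)
}

#' @export
coef.enet_fit <- function(object, ...) object$coefficients

#' Per-chromosome coefficients of the chromosome-identity model
#'
#' Extracts the mean fitted weight per chromosome from a `chrom_length`
#' fit: the overall logFC the model assumes for the entire chromosome.  A
#' positive weight marks chromosome-wide upregulation, a negative one
#' downregulation.
#'
#' @param fit an `enet_fit` with `model_id == "chrom_length"`.
#' @return data.frame with columns `chromosome` and `coefficient`, in
#'   annotation chromosome order.
#' @export
chromosome_coefficients <- function(fit) {
  stopifnot(inherits(fit, "enet_fit"))
  if (fit$model_id != "chrom_length")
    stop("parameter error: fit must be a chrom_length model")
  data.frame(chromosome = names(fit$coefficients),
             coefficient = as.numeric(fit$coefficients),
             row.names = NULL)
}

#' Pinpoint differential expression to chromosomes
#'
#' Per chromosome, the percentage of genes with uncorrected p below `alpha`
#' (strict inequality) out of all uniquely mapping genes on that
#' chromosome, split by fold-change sign.  Genes with logFC exactly 0 are
#' counted neither as up- nor as downregulated nor in the DEG total, so
#' `pct_up + pct_down == pct_deg` always holds.
#'
#' @param table a [comparison_table()] with p-values for all genes.
#' @param alpha significance threshold (default 0.05, uncorrected for
#'   comparability between very different comparisons).
#' @return data.frame with columns `chromosome`, `n_genes`, `pct_deg`,
#'   `pct_up`, `pct_down` (percentages), one row per chromosome carrying at
#'   least one gene.
#' @export
pinpoint_deg <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "comparison_table"))
  g <- table$genes
  if (anyNA(g$p_value)) stop("p_value must be present for all genes")
  chroms <- unique(g$chromosome)
  out <- do.call(rbind, lapply(chroms, function(cn) {
    sel <- g$chromosome == cn
    n <- sum(sel)
    sig <- sel & g$p_value < alpha & g$logfc != 0
    data.frame(chromosome = cn, n_genes = n,
               pct_deg = 100 * sum(sig) / n,
               pct_up = 100 * sum(sig & g$logfc > 0) / n,
               pct_down = 100 * sum(sig & g$logfc < 0) / n)
  }))
  rownames(out) <- NULL
  out
}
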