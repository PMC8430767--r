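# Internal helpers shared across the package.

#' Derive a reproducible child seed from a master seed
#'
#' Stage-level seeds are derived deterministically from a run-level master
#' seed so that partial re-runs of a pipeline reproduce the numbers of a full
#' run.  The derivation is a fixed integer hash of the master seed and a
#' stage label; results stay within the 32-bit integer range.
#'
#' @param master_seed integer master seed.
#' @param label character stage label (or an integer index).
#' @return a single integer seed.
#' @export
derive_seed <- function(master_seed, label) {
  stopifnot(length(master_seed) == 1L, is.finite(master_seed))
  h <- 0
  for (ch in utf8ToInt(paste0(as.character(label), collapse = ""))) {
    h <- (h * 31 + ch) %% 1000003
  }
  as.integer((abs(as.numeric(master_seed)) * 2654435 + h * 97 + 1) %% 2147483629)
}

# Run `expr` under a given seed without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% 2147483629))
  }
  force(expr)
}

# Merge sorted, possibly overlapping half-open intervals on one chromosome.
# `starts`/`ends` are integer vectors; returns a two-column matrix.
merge_intervals <- function(starts, ends) {
  if (length(starts) == 0L) return(matrix(numeric(0), ncol = 2L))
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1L]; me <- ends[1L]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= me) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  cbind(c(out_s, ms), c(out_e, me))
}

# Centered moving average with window `w` (shrunk near the edges), used for
# the smoothed curves of parameter sweeps.
moving_average <- function(x, w = 30L) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  w <- max(1L, min(as.integer(w), n))
  half <- (w - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half + (w - 1L) %% 2L)
    mean(x[lo:hi])
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
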