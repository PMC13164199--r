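# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. All exported stochastic operations route their seed through this.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Stratified k-fold assignment. Returns an integer vector of fold ids
# (1..k) the same length as `strata`; every stratum is spread across folds
# as evenly as possible.
make_folds <- function(strata, k, seed = NULL) {
  strata <- as.character(strata)
  n <- length(strata)
  stopifnot(k >= 2, k <= n)
  folds <- integer(n)
  with_local_seed(seed, {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  sizes <- tabulate(folds, nbins = k)
  if (any(sizes < 2)) {
    stop("stratified folding produced a fold with fewer than 2 samples; ",
         "reduce k or provide more samples per stratum")
  }
  folds
}

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x)) {
    stop(sprintf("`%s` must be a positive integer count", name))
  }
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
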