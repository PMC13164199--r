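# shared fixtures: small, fast variants of the study layout

small_design <- function(seed = 7L) {
  study_design(n_subsamples = 2, n_scans_per_subsample = 5, seed = seed)
}

noiseless_spectral_config <- function(range = "1300-2500") {
  spectral_config(range, scatter_slope_sd = 0, scatter_offset_sd = 0,
                  noise_sd = 0)
}

noiseless_volatile_config <- function() {
  volatile_config(replicate_cv = 0, injection_effect_sd = 0)
}

# Two-group peak-like matrix with `n_shift` truly shifted compounds out of
# `n_comp`, `n_rep` replicates per group; log-normal measurement noise.
# Recovery with few false positives requires enough observations that null
# correlations with the class contrast stay small: at 3 replicates per group
# any correlation-based screen admits ~4-5 chance compounds past VIP 1, so
# the planted-recovery oracle uses 10 per group.
planted_contrast <- function(n_comp = 40, n_shift = 12, n_rep = 10,
                             effect = 1.0, noise_sd = 0.12, seed = 1L) {
  withr::with_seed(seed, {
    base <- exp(runif(n_comp, log(50), log(2000)))
    shift <- c(rep(effect, n_shift), rep(0, n_comp - n_shift))
    rows <- lapply(seq_len(2 * n_rep), function(r) {
      grp <- if (r <= n_rep) 0 else 1
      base * exp(grp * shift + rnorm(n_comp, 0, noise_sd))
    })
    X <- do.call(rbind, rows)
    colnames(X) <- sprintf("cmp_%02d", seq_len(n_comp))
    list(X = X, groups = rep(c("A", "B"), each = n_rep),
         shifted = colnames(X)[seq_len(n_shift)])
  })
}
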