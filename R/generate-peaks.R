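#' Volatile-compound generator configuration
#'
#' Parameterizes the synthetic GC-IMS peak-volume model: a census of 74
#' volatile compounds split over chemical classes, a storage-trend family per
#' class, monomer/dimer pairing for a fraction of compounds, replicate noise,
#' and a per-replicate injection factor shared by all compounds including the
#' internal standard.
#'
#' Class trend families mirror the volatile chemistry of stored roasted
#' cereals: aldehydes rise steadily (lipid oxidation), acids and esters rise
#' late (fatty-acid oxidation and esterification), alcohols fall (oxidized
#' further or esterified), ketones dip mid-storage then rebound, and
#' pyrazines/furans are Maillard products created by processing that slowly
#' fade.
#'
#' @param class_counts Named integer vector of compounds per class; must sum
#'   to 74 under the emulated census.
#' @param trend_families Named character vector mapping each class to one of
#'   `"rise"`, `"fall"`, `"dip_rebound"`, `"late_rise"`, `"processing_pulse"`,
#'   `"flat"`.
#' @param dimer_fraction Proportion of compounds emitted as monomer + dimer
#'   pairs (acids and alcohols cluster most readily; the fraction applies
#'   uniformly here).
#' @param replicate_cv Relative SD of per-compound replicate noise
#'   (log-normal).
#' @param injection_effect_sd SD of the log-normal per-replicate injection
#'   factor applied to every compound including the internal standard.
#' @param is_volume Expected internal-standard volume (constant across
#'   samples).
#'
#' @return An object of class `volatile_config`.
#' @export
volatile_config <- function(class_counts = c(aldehydes = 19, alcohols = 18,
                                             ketones = 13, esters = 9,
                                             acids = 6, pyrazines = 3,
                                             furans = 2, other = 4),
                            trend_families = c(aldehydes = "rise",
                                               alcohols = "fall",
                                               ketones = "dip_rebound",
                                               esters = "late_rise",
                                               acids = "late_rise",
                                               pyrazines = "processing_pulse",
                                               furans = "processing_pulse",
                                               other = "flat"),
                            dimer_fraction = 0.4,
                            replicate_cv = 0.05,
                            injection_effect_sd = 0.10,
                            is_volume = 1000) {
  if (sum(class_counts) != 74) {
    stop(sprintf("class counts must sum to 74 (got %d)", sum(class_counts)))
  }
  if (!setequal(names(class_counts), names(trend_families))) {
    stop("`trend_families` must name exactly the classes in `class_counts`")
  }
  fams <- c("rise", "fall", "dip_rebound", "late_rise", "processing_pulse",
            "flat")
  if (!all(trend_families %in% fams)) {
    stop("unknown trend family; allowed: ", paste(fams, collapse = ", "))
  }
  if (replicate_cv < 0 || injection_effect_sd < 0) {
    stop("replicate_cv and injection_effect_sd must be non-negative")
  }
  if (dimer_fraction < 0 || dimer_fraction > 1) {
    stop("dimer_fraction must be in [0, 1]")
  }
  structure(
    list(class_counts = class_counts, trend_families = trend_families,
         dimer_fraction = dimer_fraction, replicate_cv = replicate_cv,
         injection_effect_sd = injection_effect_sd, is_volume = is_volume),
    class = "volatile_config"
  )
}

# Expected (noise-free) relative abundance of one compound at a storage
# state. `jit` perturbs the family's shape parameters so compounds within a
# class are not clones; monotone families stay monotone for |jit| < 1.
trend_value <- function(family, months, processed, jit = 0) {
  switch(family,
    rise = {
      raw <- 0.6
      if (!processed) raw
      else raw + (1.8 + 0.4 * jit) / (1 + exp(-(months - 18 - 4 * jit) / 8))
    },
    late_rise = {
      raw <- 0.5
      if (!processed) raw
      else raw + (2.5 + 0.5 * jit) / (1 + exp(-(months - 35 - 4 * jit) / 7))
    },
    fall = {
      if (!processed) 1.6 + 0.2 * jit
      else 0.4 + (1.2 + 0.2 * jit) * exp(-months / (18 + 4 * jit))
    },
    dip_rebound = {
      if (!processed) 1
      else 1 - (0.45 + 0.1 * jit) * exp(-((months - 14) / 10)^2) +
        0.004 * months
    },
    processing_pulse = {
      if (!processed) 0.15
      else 0.3 + (1.5 + 0.3 * jit) * exp(-months / 25)
    },
    flat = 1,
    stop("unknown trend family: ", family)
  )
}

#' Generate a synthetic GC-IMS peak table
#'
#' Emits volumes for 74 identified compounds plus one internal-standard row,
#' across all design samples and replicate injections. Each replicate carries
#' one log-normal injection factor multiplying every compound (including the
#' internal standard), so internal-standard normalization cancels it exactly;
#' per-compound replicate noise is controlled by `replicate_cv`. A fraction of
#' compounds appears as monomer/dimer pairs sharing one underlying trend up to
#' a fixed per-compound ratio. Deterministic given `design$seed`.
#'
#' @param design A [study_design()].
#' @param config A [volatile_config()].
#' @return A [peak_table()] with `74 + n_dimers + 1` rows (each dimer is an
#'   extra row sharing its monomer's CAS) and `n_samples * n_gcims_replicates`
#'   columns.
#' @examples
#' pt <- generate_peak_table(study_design(), volatile_config())
#' sum(pt$compounds$form == "M") - 1  # 74 identified compounds (minus IS row)
#' @export
generate_peak_table <- function(design, config) {
  stopifnot(inherits(design, "study_design"), inherits(config, "volatile_config"))
  classes <- rep(names(config$class_counts), config$class_counts)
  n_comp <- length(classes)  # 74

  n_samp <- length(design$sample_labels)
  n_rep <- design$n_gcims_replicates
  n_cols <- n_samp * n_rep
  col_meta <- data.frame(sample = rep(design$sample_labels, each = n_rep),
                         replicate = rep(seq_len(n_rep), n_samp))

  with_local_seed(design$seed + 1L, {
    base <- exp(stats::runif(n_comp, log(100), log(5000)))
    jit <- stats::runif(n_comp, -0.8, 0.8)
    is_dimeric <- stats::runif(n_comp) < config$dimer_fraction
    dimer_ratio <- stats::runif(n_comp, 0.25, 0.8)

    # compound rows: every compound as monomer, plus dimer rows
    idx_counter <- stats::ave(seq_along(classes), classes, FUN = seq_along)
    name <- sprintf("%s_%02d", sub("s$", "", classes), idx_counter)
    cas <- sprintf("SYN-%03d", seq_len(n_comp))
    compounds <- data.frame(
      compound = c(paste0(name, "-M"), paste0(name[is_dimeric], "-D"),
                   "2-octanol-D4 (IS)"),
      cas = c(cas, cas[is_dimeric], "IS-0001"),
      form = c(rep("M", n_comp), rep("D", sum(is_dimeric)), "M"),
      class = c(classes, classes[is_dimeric], "internal_standard"),
      stringsAsFactors = FALSE
    )

    # expected volume per monomer compound x sample
    expected <- matrix(0, n_comp, n_samp)
    for (i in seq_len(n_comp)) {
      fam <- config$trend_families[[classes[i]]]
      for (s in seq_len(n_samp)) {
        expected[i, s] <- base[i] * trend_value(fam, design$storage_months[s],
                                                design$processed[s], jit[i])
      }
    }
    expected_all <- rbind(expected,
                          expected[is_dimeric, , drop = FALSE] *
                            dimer_ratio[is_dimeric],
                          matrix(config$is_volume, 1, n_samp))

    injection <- exp(stats::rnorm(n_cols, 0, config$injection_effect_sd))
    n_rows <- nrow(expected_all)
    volumes <- matrix(0, n_rows, n_cols)
    for (j in seq_len(n_cols)) {
      s <- (j - 1L) %/% n_rep + 1L
      noise <- if (config$replicate_cv > 0) {
        exp(stats::rnorm(n_rows, 0, config$replicate_cv))
      } else rep(1, n_rows)
      volumes[, j] <- expected_all[, s] * injection[j] * noise
    }
  })

  peak_table(compounds, volumes, col_meta,
             internal_standard = "2-octanol-D4 (IS)")
}
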