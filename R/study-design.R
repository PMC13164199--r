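#' Storage-study design
#'
#' Describes the sampling layout of the storage experiment the synthetic
#' generators emulate: one raw sample (`S`) plus six processed samples stored
#' for increasing durations, each measured as 5 subsamples x 10 NIRS scans
#' (50 spectra per sample) and 3 GC-IMS replicates.
#'
#' @param storage_months Integer months of storage for the processed samples,
#'   strictly increasing. Default `c(2, 4, 12, 29, 46, 56)`.
#' @param include_raw Logical; include the unprocessed raw sample `S`
#'   (months coded 0, used only for the processing contrast, never for the
#'   deterioration index).
#' @param n_subsamples Subsamples per sample scanned on the spectrometer.
#' @param n_scans_per_subsample Spectra collected per subsample.
#' @param n_gcims_replicates Parallel GC-IMS measurements per sample.
#' @param seed Integer RNG seed attached to the design; generators derive
#'   their randomness from it.
#'
#' @return An object of class `study_design` with fields `sample_labels`,
#'   `storage_months`, `processed`, and the replication counts.
#' @examples
#' d <- study_design()
#' d$sample_labels   # "S" "P2" "P4" "P12" "P29" "P46" "P56"
#' @export
study_design <- function(storage_months = c(2, 4, 12, 29, 46, 56),
                         include_raw = TRUE,
                         n_subsamples = 5,
                         n_scans_per_subsample = 10,
                         n_gcims_replicates = 3,
                         seed = 1L) {
  storage_months <- as.integer(storage_months)
  if (length(storage_months) < 1L || any(storage_months <= 0)) {
    stop("`storage_months` must be positive integers")
  }
  if (is.unsorted(storage_months, strictly = TRUE)) {
    stop("`storage_months` must be strictly increasing")
  }
  stop_if_not_scalar_count(n_subsamples, "n_subsamples")
  stop_if_not_scalar_count(n_scans_per_subsample, "n_scans_per_subsample")
  stop_if_not_scalar_count(n_gcims_replicates, "n_gcims_replicates")

  labels <- paste0("P", storage_months)
  months <- storage_months
  processed <- rep(TRUE, length(labels))
  if (include_raw) {
    labels <- c("S", labels)
    months <- c(0L, months)
    processed <- c(FALSE, processed)
  }
  structure(
    list(
      sample_labels = labels,
      storage_months = months,
      processed = processed,
      n_subsamples = as.integer(n_subsamples),
      n_scans_per_subsample = as.integer(n_scans_per_subsample),
      n_gcims_replicates = as.integer(n_gcims_replicates),
      seed = as.integer(seed)
    ),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("Storage-study design\n")
  cat("  samples: ", paste(x$sample_labels, collapse = " "), "\n", sep = "")
  cat(sprintf("  %d subsamples x %d scans = %d spectra/sample; %d GC-IMS replicates\n",
              x$n_subsamples, x$n_scans_per_subsample,
              x$n_subsamples * x$n_scans_per_subsample, x$n_gcims_replicates))
  invisible(x)
}

#' Ground-truth deterioration score for a design
#'
#' A monotone function of storage months over the processed samples, scaled so
#' the index spans about 6 dimensionless units between the earliest and latest
#' storage points. Used as ground truth in parameter-recovery tests of the
#' composite-index pipeline; it is not part of the measurement model.
#'
#' @param design A [study_design()].
#' @return Named numeric vector, one value per processed sample.
#' @examples
#' true_index(study_design())
#' @export
true_index <- function(design) {
  stopifnot(inherits(design, "study_design"))
  m <- design$storage_months[design$processed]
  lab <- design$sample_labels[design$processed]
  lo <- min(m); hi <- max(m)
  if (hi == lo) {
    idx <- rep(0, length(m))
  } else {
    idx <- 6 * (m - lo) / (hi - lo)
  }
  names(idx) <- lab
  idx
}
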