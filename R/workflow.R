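#' Workflow configuration
#'
#' Collects every tunable of the end-to-end pipeline with the study's
#' defaults: the storage design, both instrument ranges, the volatile
#' generator, the VIP screening threshold (1.0, highlight at 2.0), the RPD
#' rubric (3.0), the latent-variable grid (1-10, 5-fold CV), and the
#' permutation count (200, Q2-intercept threshold 0.05).
#'
#' @param seed Master seed; stage seeds derive from it.
#' @param design A [study_design()] (defaults to the emulated study layout).
#' @param ranges Instrument ranges to run (default both).
#' @param volatile A [volatile_config()].
#' @param n_permutations Permutation iterations (default 200).
#' @param vip_threshold Marker-screening VIP cutoff (default 1.0).
#' @param lv_grid Latent-variable grid (default `1:10`).
#' @param cv_k Folds for PLSR cross-validation (default 5).
#' @param split_ratio Training fraction (default 0.8).
#' @param sg_window,sg_polyorder Savitzky-Golay settings shared by all
#'   derivative methods.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       design = NULL,
                       ranges = c("900-1700", "1300-2500"),
                       volatile = volatile_config(),
                       n_permutations = 200,
                       vip_threshold = 1.0,
                       lv_grid = 1:10,
                       cv_k = 5,
                       split_ratio = 0.8,
                       sg_window = 11,
                       sg_polyorder = 2) {
  seed <- as.integer(seed)
  if (is.null(design)) design <- study_design(seed = seed)
  ranges <- match.arg(ranges, several.ok = TRUE)
  stopifnot(n_permutations >= 1, vip_threshold > 0,
            split_ratio > 0, split_ratio < 1)
  structure(
    list(seed = seed, design = design, ranges = ranges, volatile = volatile,
         n_permutations = as.integer(n_permutations),
         vip_threshold = vip_threshold, lv_grid = lv_grid, cv_k = cv_k,
         split_ratio = split_ratio, sg_window = sg_window,
         sg_polyorder = sg_polyorder),
    class = "run_config"
  )
}

#' Run the full GC-IMS-guided NIRS calibration workflow
#'
#' Executes the complete experiment graph on synthetic data: generate the
#' GC-IMS peak table, normalize to the internal standard and deduplicate
#' monomer/dimer forms, screen markers for the processing contrast (raw vs
#' earliest processed sample) and the storage contrast (earliest vs latest
#' processed sample), build the composite flavor and deterioration indices,
#' then for every configured instrument range calibrate both indices across
#' all seven preprocessing methods and permutation-validate the best model of
#' each block. Fully deterministic given the configuration seed.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, marker tables, index
#'   tables, calibration reports and a JSON manifest are written there as
#'   CSV/JSON.
#' @return A list bundle with elements `markers` (per contrast), `indices`
#'   (per kind), `calibrations` (per range x kind `calibration_report`),
#'   `permutations` (per range x kind `permutation_report`) and `config`.
#' @export
run_workflow <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  design <- config$design

  ## GC-IMS side -----------------------------------------------------------
  raw_table <- generate_peak_table(design, config$volatile)
  norm_table <- normalize_to_internal_standard(raw_table)
  dedup <- deduplicate_forms(norm_table)

  labels <- design$sample_labels
  raw_lab <- labels[!design$processed][1]
  proc_labs <- labels[design$processed]
  first_proc <- proc_labs[1]
  last_proc <- proc_labs[length(proc_labs)]

  contrast_matrix <- function(samples) {
    cols <- dedup$col_meta$sample %in% samples
    t(dedup$volumes[, cols, drop = FALSE])
  }
  contrast_groups <- function(samples) {
    dedup$col_meta$sample[dedup$col_meta$sample %in% samples]
  }

  markers <- list(
    flavor = screen_markers(contrast_matrix(c(raw_lab, first_proc)),
                            contrast_groups(c(raw_lab, first_proc)),
                            threshold = config$vip_threshold,
                            k_folds = 3, seed = config$seed),
    deterioration = screen_markers(contrast_matrix(c(first_proc, last_proc)),
                                   contrast_groups(c(first_proc, last_proc)),
                                   threshold = config$vip_threshold,
                                   k_folds = 3, seed = config$seed)
  )
  if (nrow(markers$flavor) == 0 || nrow(markers$deterioration) == 0) {
    stop("marker screening returned an empty set; check generator settings")
  }

  flavor_response <- stats::setNames(as.numeric(design$processed), labels)
  det_response <- stats::setNames(design$storage_months[design$processed],
                                  proc_labs)
  indices <- list(
    flavor = build_index(dedup, flavor_response, markers$flavor$compound,
                         kind = "flavor"),
    deterioration = build_index(dedup, det_response,
                                markers$deterioration$compound,
                                kind = "deterioration")
  )

  ## NIRS side -------------------------------------------------------------
  calibrations <- list()
  permutations <- list()
  for (range in config$ranges) {
    spec_cfg <- spectral_config(range)
    spectra <- generate_spectra(design, spec_cfg)
    specs <- all_preprocess_specs(sg_window = config$sg_window,
                                  sg_polyorder = config$sg_polyorder)
    for (kind in c("flavor", "deterioration")) {
      sub <- if (kind == "deterioration") {
        subset_spectra(spectra, which(spectra$meta$processed))
      } else spectra
      split <- make_split(sub, ratio = config$split_ratio, seed = config$seed)
      rep_name <- paste(kind, range, sep = ".")
      cal <- calibrate_index(sub, indices[[kind]], preprocess_specs = specs,
                             lv_grid = config$lv_grid, cv_k = config$cv_k,
                             split = split, seed = config$seed)
      calibrations[[rep_name]] <- cal
      best <- attr(cal, "models")[[cal$preprocessing[cal$best]]]
      permutations[[rep_name]] <- permutation_test(
        best$X_train, best$y_train, n_lv = best$model$n_lv,
        n_iter = config$n_permutations, cv_k = config$cv_k,
        seed = config$seed,
        strata = as.character(subset_spectra(sub, split$train)$meta$sample))
    }
  }

  bundle <- list(markers = markers, indices = indices,
                 calibrations = calibrations, permutations = permutations,
                 dedup_log = attr(dedup, "dedup_log"), config = config)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

# Write the report bundle as inspectable CSV/JSON files.
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (k in names(bundle$markers)) {
    utils::write.csv(bundle$markers[[k]],
                     file.path(out_dir, sprintf("markers_%s.csv", k)),
                     row.names = FALSE)
  }
  idx_tab <- do.call(rbind, lapply(names(bundle$indices), function(k) {
    ci <- bundle$indices[[k]]
    data.frame(sample = names(ci$values), kind = ci$kind,
               value = unname(ci$values), n_markers = length(ci$markers))
  }))
  utils::write.csv(idx_tab, file.path(out_dir, "indices.csv"),
                   row.names = FALSE)
  cal_tab <- do.call(rbind, lapply(names(bundle$calibrations), function(k) {
    cbind(block = k, as.data.frame(bundle$calibrations[[k]]))
  }))
  utils::write.csv(cal_tab, file.path(out_dir, "calibration_report.csv"),
                   row.names = FALSE)
  perm_tab <- do.call(rbind, lapply(names(bundle$permutations), function(k) {
    p <- bundle$permutations[[k]]
    data.frame(block = k, n_iter = p$n_iter, n_lv = p$n_lv,
               original_r2 = p$original_r2, original_q2 = p$original_q2,
               r2_intercept = p$r2_intercept, q2_intercept = p$q2_intercept,
               pass = p$pass)
  }))
  utils::write.csv(perm_tab, file.path(out_dir, "permutation_report.csv"),
                   row.names = FALSE)
  manifest <- list(seed = bundle$config$seed,
                   ranges = bundle$config$ranges,
                   n_permutations = bundle$config$n_permutations,
                   vip_threshold = bundle$config$vip_threshold,
                   blocks = names(bundle$calibrations))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
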