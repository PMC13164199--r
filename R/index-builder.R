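#' Normalize peak volumes to the internal standard
#'
#' Divides every compound's volume by the internal-standard volume of the
#' same replicate injection, cancelling per-replicate injection variability
#' and instrumental drift exactly, then removes the internal-standard row
#' from the analyte set.
#'
#' @param table A [peak_table()] whose `internal_standard` row is present.
#' @return A normalized [peak_table()] (internal standard removed,
#'   `internal_standard = NA`).
#' @export
normalize_to_internal_standard <- function(table) {
  stopifnot(inherits(table, "peak_table"))
  if (is.na(table$internal_standard)) {
    stop("table has no internal-standard row (already normalized?)")
  }
  is_row <- which(table$compounds$compound == table$internal_standard)
  is_vol <- table$volumes[is_row, ]
  bad <- which(!is.finite(is_vol) | is_vol <= 0)
  if (length(bad) > 0) {
    stop(sprintf("internal standard missing or non-positive in replicate (sample %s, replicate %s)",
                 table$col_meta$sample[bad[1]], table$col_meta$replicate[bad[1]]))
  }
  vols <- sweep(table$volumes[-is_row, , drop = FALSE], 2, is_vol, "/")
  peak_table(table$compounds[-is_row, , drop = FALSE], vols, table$col_meta,
             internal_standard = NA)
}

#' Retain one ion form per compound
#'
#' Compounds detected as both monomer (M) and dimer (D) carry redundant,
#' collinear signals. For each CAS with both forms the form with the higher
#' stability ratio (mean volume / replicate CV) is retained; ties break
#' toward the monomer. The Spearman correlation between the two forms'
#' per-sample mean profiles is recorded as a consistency check, and the
#' discarded forms are listed in the attached log.
#'
#' @param table A normalized [peak_table()].
#' @return A [peak_table()] with at most one row per CAS; attribute
#'   `"dedup_log"` is a `data.frame` (cas, kept, discarded, profile
#'   correlation).
#' @export
deduplicate_forms <- function(table) {
  stopifnot(inherits(table, "peak_table"))
  cmp <- table$compounds
  samples <- table$col_meta$sample
  keep <- rep(TRUE, nrow(cmp))
  log_rows <- list()

  # replicate CV within samples, averaged over samples
  replicate_cv_of <- function(v) {
    cvs <- tapply(v, samples, function(z) {
      m <- mean(z)
      if (m == 0) return(Inf)
      stats::sd(z) / m
    })
    mean(unlist(cvs))
  }
  sample_profile <- function(v) {
    tapply(v, samples, mean)[unique(samples)]
  }

  for (cas in unique(cmp$cas)) {
    rows <- which(cmp$cas == cas)
    if (length(rows) < 2) next
    forms <- cmp$form[rows]
    # stability ratio mean/CV per form; degenerate CV=0 treated as maximal
    stab <- vapply(rows, function(r) {
      v <- table$volumes[r, ]
      cv <- replicate_cv_of(v)
      if (cv == 0) Inf else mean(v) / cv
    }, numeric(1))
    best <- which(stab == max(stab))
    if (length(best) > 1) best <- best[forms[best] == "M"][1] %||% best[1]
    if (is.na(best)) best <- 1L
    kept_row <- rows[best]
    dropped <- setdiff(rows, kept_row)
    keep[dropped] <- FALSE
    prof <- vapply(rows, function(r) sample_profile(table$volumes[r, ]),
                   numeric(length(unique(samples))))
    rho <- suppressWarnings(
      stats::cor(prof[, 1], prof[, 2], method = "spearman"))
    log_rows[[cas]] <- data.frame(
      cas = cas,
      kept = cmp$compound[kept_row],
      discarded = paste(cmp$compound[dropped], collapse = ";"),
      profile_spearman = rho,
      stringsAsFactors = FALSE
    )
  }
  out <- peak_table(cmp[keep, , drop = FALSE],
                    table$volumes[keep, , drop = FALSE],
                    table$col_meta, internal_standard = table$internal_standard)
  attr(out, "dedup_log") <- if (length(log_rows)) {
    do.call(rbind, c(log_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(cas = character(), kept = character(),
               discarded = character(), profile_spearman = numeric())
  }
  out
}

# Replicate-averaged sample x compound matrix from a peak table.
sample_means <- function(table, compounds = NULL) {
  cmp_idx <- if (is.null(compounds)) {
    seq_len(nrow(table$volumes))
  } else {
    idx <- match(compounds, table$compounds$compound)
    if (anyNA(idx)) {
      stop("marker(s) absent from the table: ",
           paste(compounds[is.na(idx)], collapse = ", "))
    }
    idx
  }
  samples <- unique(table$col_meta$sample)
  M <- t(vapply(samples, function(s) {
    rowMeans(table$volumes[cmp_idx, table$col_meta$sample == s, drop = FALSE])
  }, numeric(length(cmp_idx))))
  rownames(M) <- samples
  colnames(M) <- table$compounds$compound[cmp_idx]
  M
}

#' Build a composite flavor or deterioration index
#'
#' Fits a PLS1 model of the selected volatile markers (replicate-averaged,
#' column-centered and unit-variance-scaled) against the response -- storage
#' months for the deterioration index on processed samples, or the 0/1
#' processing stage for the flavor index across all samples -- and takes the
#' first latent-variable score per sample as a single continuous,
#' dimensionless index. The sign is oriented so the index correlates
#' positively with the response; the fitted model is stored so new samples
#' can be projected without refitting.
#'
#' @param table A normalized, deduplicated [peak_table()].
#' @param response Named numeric vector: response value per sample (names =
#'   sample labels present in the table). Samples not named are excluded
#'   (e.g. the raw sample for the deterioration index).
#' @param markers Character vector of marker compounds (e.g. from
#'   [screen_markers()]); must be present in the table.
#' @param kind `"deterioration"` or `"flavor"` (metadata label).
#' @param n_lv Latent variables whose scores are summed into the index
#'   (default 1, the single-score convention).
#' @return An object of class `composite_index` with fields `values` (named
#'   per-sample scores), `kind`, `markers`, `orientation` (+1/-1) and the
#'   underlying `pls_model`.
#' @export
build_index <- function(table, response, markers,
                        kind = c("deterioration", "flavor"), n_lv = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(table, "peak_table"))
  if (length(markers) == 0) stop("marker set is empty")
  resp_samples <- names(response)
  if (is.null(resp_samples)) stop("`response` must be named by sample label")
  if (length(resp_samples) < 3) stop("need at least 3 samples to build an index")
  if (stats::sd(response) == 0) stop("constant response: index undefined")

  M <- sample_means(table, markers)
  missing <- setdiff(resp_samples, rownames(M))
  if (length(missing)) {
    stop("response names a sample absent from the table: ",
         paste(missing, collapse = ", "))
  }
  M <- M[resp_samples, , drop = FALSE]

  model <- fit_pls1(M, as.numeric(response),
                    n_lv = min(n_lv, nrow(M) - 1L, ncol(M)), scale_x = TRUE)
  scores <- rowSums(pls_scores(model, M))
  orientation <- if (stats::cor(scores, response) >= 0) 1 else -1
  values <- orientation * scores
  names(values) <- resp_samples

  structure(
    list(values = values, kind = kind, markers = colnames(M),
         orientation = orientation, model = model,
         response = stats::setNames(as.numeric(response), resp_samples)),
    class = "composite_index"
  )
}

#' @export
print.composite_index <- function(x, ...) {
  cat(sprintf("composite %s index over %d samples (%d markers)\n",
              x$kind, length(x$values), length(x$markers)))
  print(round(x$values, 3))
  invisible(x)
}

#' Project new samples onto a fitted composite index
#'
#' Applies the stored centering/scaling and latent weights of a
#' [build_index()] model to new replicate-averaged marker volumes.
#'
#' @param index A [composite_index()].
#' @param table A normalized [peak_table()] containing the index's markers.
#' @return Named numeric vector of index values per sample in `table`.
#' @export
project_index <- function(index, table) {
  stopifnot(inherits(index, "composite_index"), inherits(table, "peak_table"))
  M <- sample_means(table, index$markers)
  scores <- rowSums(pls_scores(index$model, M))
  stats::setNames(index$orientation * scores, rownames(M))
}
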