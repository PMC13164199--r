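#' GC-IMS peak-volume table
#'
#' Holds per-compound peak volumes across samples and replicate injections,
#' with compound metadata (CAS, monomer/dimer form, chemical class) and the
#' identity of the spiked internal standard used for normalization.
#'
#' @param compounds `data.frame` with columns `compound`, `cas`, `form`
#'   (`"M"` or `"D"`), `class`; one row per table row.
#' @param volumes Numeric matrix, compounds x (sample, replicate) columns,
#'   strictly positive.
#' @param col_meta `data.frame` with columns `sample`, `replicate`, one row
#'   per volume column.
#' @param internal_standard Compound name of the internal-standard row, or
#'   `NA` if it has already been removed by normalization.
#'
#' @return An object of class `peak_table`.
#' @export
peak_table <- function(compounds, volumes, col_meta, internal_standard = NA) {
  compounds <- as.data.frame(compounds)
  volumes <- as.matrix(volumes)
  col_meta <- as.data.frame(col_meta)
  stopifnot(all(c("compound", "cas", "form", "class") %in% names(compounds)),
            all(c("sample", "replicate") %in% names(col_meta)))
  if (nrow(compounds) != nrow(volumes)) {
    stop("compound metadata rows must match volume matrix rows")
  }
  if (nrow(col_meta) != ncol(volumes)) {
    stop("column metadata rows must match volume matrix columns")
  }
  if (any(!is.finite(volumes)) || any(volumes <= 0)) {
    stop("peak volumes must be finite and strictly positive")
  }
  if (!all(compounds$form %in% c("M", "D"))) {
    stop("compound form must be 'M' (monomer) or 'D' (dimer)")
  }
  if (!is.na(internal_standard) &&
      !internal_standard %in% compounds$compound) {
    stop(sprintf("internal standard '%s' not present in the table",
                 internal_standard))
  }
  rownames(volumes) <- compounds$compound
  structure(
    list(compounds = compounds, volumes = volumes, col_meta = col_meta,
         internal_standard = internal_standard),
    class = "peak_table"
  )
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("peak_table: %d compound rows x %d (sample, replicate) columns\n",
              nrow(x$volumes), ncol(x$volumes)))
  cat("  samples:", paste(unique(x$col_meta$sample), collapse = " "), "\n")
  if (!is.na(x$internal_standard)) {
    cat("  internal standard:", x$internal_standard, "\n")
  }
  invisible(x)
}

#' Write / read peak tables as long CSV
#'
#' Long layout: one row per (compound, sample, replicate) with columns
#' `compound, cas, form, class, sample, replicate, volume`.
#'
#' @param x A [peak_table()].
#' @param path File path.
#' @return `write_peak_table_csv` returns `path` invisibly;
#'   `read_peak_table_csv` returns a [peak_table()].
#' @param internal_standard Name of the internal-standard compound in the
#'   file (pass `NA` for an already-normalized table).
#' @export
write_peak_table_csv <- function(x, path) {
  stopifnot(inherits(x, "peak_table"))
  long <- do.call(rbind, lapply(seq_len(ncol(x$volumes)), function(j) {
    data.frame(x$compounds,
               sample = x$col_meta$sample[j],
               replicate = x$col_meta$replicate[j],
               volume = x$volumes[, j],
               row.names = NULL)
  }))
  utils::write.csv(long, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_peak_table_csv
#' @export
read_peak_table_csv <- function(path, internal_standard = NA) {
  long <- utils::read.csv(path, fileEncoding = "UTF-8",
                          stringsAsFactors = FALSE)
  need <- c("compound", "cas", "form", "class", "sample", "replicate", "volume")
  if (!all(need %in% names(long))) {
    stop("long CSV must have columns: ", paste(need, collapse = ", "))
  }
  key <- paste(long$sample, long$replicate, sep = "\r")
  cols <- unique(key)
  comp_rows <- !duplicated(long$compound)
  compounds <- long[comp_rows, c("compound", "cas", "form", "class")]
  volumes <- matrix(NA_real_, nrow(compounds), length(cols),
                    dimnames = list(compounds$compound, NULL))
  for (j in seq_along(cols)) {
    sub <- long[key == cols[j], ]
    volumes[sub$compound, j] <- sub$volume
  }
  first <- match(cols, key)
  col_meta <- data.frame(sample = long$sample[first],
                         replicate = long$replicate[first])
  peak_table(compounds, volumes, col_meta, internal_standard)
}
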