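#' Spectra container
#'
#' Bundles a wavelength grid, an absorbance matrix (one row per recorded
#' spectrum) and per-spectrum metadata. All preprocessing and calibration
#' functions consume and return this container.
#'
#' @param wavelengths Strictly increasing numeric grid in nm.
#' @param absorbance Numeric matrix, spectra x wavelengths, unitless
#'   (log10(1/R)); may hold reflectance when `unit = "reflectance"`.
#' @param meta `data.frame` with one row per spectrum; columns `sample`,
#'   `processed`, `months`, `subsample`, `scan` (extra columns pass through).
#' @param unit Either `"absorbance"` or `"reflectance"`.
#'
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(wavelengths, absorbance, meta,
                        unit = c("absorbance", "reflectance")) {
  unit <- match.arg(unit)
  wavelengths <- as.numeric(wavelengths)
  absorbance <- as.matrix(absorbance)
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    stop("`wavelengths` must be strictly increasing")
  }
  if (ncol(absorbance) != length(wavelengths)) {
    stop(sprintf("absorbance has %d columns but the grid has %d wavelengths",
                 ncol(absorbance), length(wavelengths)))
  }
  if (nrow(absorbance) != nrow(meta)) {
    stop("metadata row count must equal the number of spectra")
  }
  if (any(!is.finite(absorbance))) {
    stop("absorbance matrix contains non-finite entries")
  }
  structure(
    list(wavelengths = wavelengths, absorbance = absorbance,
         meta = as.data.frame(meta), unit = unit),
    class = "spectra_set"
  )
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("spectra_set: %d spectra x %d wavelengths (%.0f-%.0f nm), unit = %s\n",
              nrow(x$absorbance), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths), x$unit))
  cat("  samples:", paste(unique(x$meta$sample), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

#' Subset a spectra set by row
#'
#' Keeps absorbance rows and metadata aligned; used e.g. to drop raw-sample
#' spectra before a deterioration-index calibration.
#'
#' @param x A [spectra_set()].
#' @param idx Integer or logical row index.
#' @return A [spectra_set()] with the selected spectra.
#' @export
subset_spectra <- function(x, idx) {
  spectra_set(x$wavelengths, x$absorbance[idx, , drop = FALSE],
              x$meta[idx, , drop = FALSE], unit = x$unit)
}

#' Write / read spectra as wide CSV
#'
#' The wide layout has the metadata columns first, then one column per
#' wavelength (header = wavelength in nm). UTF-8, "." decimal separator.
#'
#' @param x A [spectra_set()].
#' @param path File path.
#' @return `write_spectra_csv` returns `path` invisibly; `read_spectra_csv`
#'   returns a [spectra_set()].
#' @export
write_spectra_csv <- function(x, path) {
  stopifnot(inherits(x, "spectra_set"))
  wide <- cbind(x$meta,
                as.data.frame(x$absorbance,
                              col.names = paste0("wl_", x$wavelengths)))
  names(wide) <- c(names(x$meta), paste0("wl_", format(x$wavelengths,
                                                       trim = TRUE,
                                                       scientific = FALSE)))
  utils::write.csv(wide, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  wide <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  wl_cols <- grep("^wl_", names(wide))
  if (length(wl_cols) == 0) stop("no wavelength columns (prefix 'wl_') found")
  wl <- as.numeric(sub("^wl_", "", names(wide)[wl_cols]))
  spectra_set(wl, as.matrix(wide[, wl_cols]), wide[, -wl_cols, drop = FALSE])
}
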