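#' Convert diffuse reflectance to absorbance
#'
#' Elementwise `a = log10(1/R)`, the standard NIRS absorbance transform for
#' diffuse-reflectance measurements against a white reference.
#'
#' @param reflectance Numeric matrix (or vector) of reflectance values in
#'   (0, 1].
#' @return Matrix of absorbance values, same shape.
#' @examples
#' reflectance_to_absorbance(c(1, 0.1, 0.5))  # 0, 1, ~0.30103
#' @export
reflectance_to_absorbance <- function(reflectance) {
  r <- as.matrix(reflectance)
  bad <- which(!is.finite(r) | r <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("reflectance must be > 0; first offending cell [%d, %d] = %s",
                 bad[1, 1], bad[1, 2], format(r[bad[1, 1], bad[1, 2]])))
  }
  log10(1 / r)
}

#' Standard normal variate transform
#'
#' Centers and scales each spectrum (row) to mean 0 and sample SD 1
#' (n-1 denominator), the usual per-spectrum scatter correction.
#'
#' @param x Numeric matrix (spectra x wavelengths) or a single spectrum.
#' @return Transformed matrix of the same shape.
#' @export
snv <- function(x) {
  m <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(m) < 2) stop("SNV needs spectra of length >= 2")
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  if (any(sdv == 0)) {
    stop("SNV undefined for a constant spectrum (zero standard deviation)")
  }
  out <- (m - mu) / sdv
  if (is.matrix(x)) out else drop(out)
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum by ordinary least squares
#' and inverts the fitted additive/multiplicative distortion:
#' `corrected = (x - intercept) / slope`. The reference defaults to the
#' column mean of the input (training) matrix and is returned so held-out
#' spectra can be corrected against the training reference.
#'
#' @param x Numeric matrix, spectra x wavelengths.
#' @param reference Optional reference spectrum; defaults to `colMeans(x)`.
#' @return Corrected matrix with the reference attached as attribute
#'   `"reference"`.
#' @export
msc <- function(x, reference = NULL) {
  x <- as.matrix(x)
  if (is.null(reference)) {
    if (nrow(x) < 2) stop("MSC needs >= 2 spectra to form a mean reference")
    reference <- colMeans(x)
  }
  reference <- as.numeric(reference)
  if (length(reference) != ncol(x)) {
    stop("reference length must equal the number of wavelengths")
  }
  ref_c <- reference - mean(reference)
  ss <- sum(ref_c^2)
  if (ss == 0) stop("MSC reference has zero variance")
  out <- x
  for (i in seq_len(nrow(x))) {
    b <- sum((x[i, ] - mean(x[i, ])) * ref_c) / ss
    a <- mean(x[i, ]) - b * mean(reference)
    if (b == 0) stop("MSC slope is zero for spectrum ", i)
    out[i, ] <- (x[i, ] - a) / b
  }
  attr(out, "reference") <- reference
  out
}

#' Savitzky-Golay smoothing / derivative filter
#'
#' Local least-squares polynomial filtering via [signal::sgolayfilt()];
#' `deriv = 1` returns the first derivative per nm (scaled by the grid
#' spacing). Edges are handled by the boundary polynomial fits, so
#' polynomials of degree <= `polyorder` are reproduced exactly everywhere.
#'
#' @param x Matrix (spectra x wavelengths) or single spectrum.
#' @param window Odd window width in points.
#' @param polyorder Polynomial order, `< window`.
#' @param deriv Derivative order, 0 or 1.
#' @param spacing Grid spacing in nm (derivatives are per nm).
#' @return Filtered matrix/vector, same shape as the input.
#' @export
savgol <- function(x, window = 11, polyorder = 2, deriv = 0, spacing = 1) {
  if (window %% 2 == 0) stop("`window` must be odd")
  if (polyorder >= window) stop("`polyorder` must be smaller than `window`")
  if (!deriv %in% c(0, 1)) stop("`deriv` must be 0 or 1")
  m <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (window > ncol(m)) stop("`window` exceeds the spectrum length")
  out <- t(apply(m, 1, function(row) {
    signal::sgolayfilt(row, p = polyorder, n = window, m = deriv, ts = spacing)
  }))
  if (is.matrix(x)) out else drop(out)
}

#' Min-Max scaling with stored training statistics
#'
#' Scales each wavelength to `(x - min) / (max - min)` using per-column
#' minima/maxima learned from the training matrix; held-out values may fall
#' outside [0, 1]. A constant column is mapped to 0 with a warning.
#'
#' @param x Numeric matrix.
#' @param fit_stats Optional list with `min` and `max` vectors from a
#'   previous call (training statistics); when omitted they are computed
#'   from `x`.
#' @return List with elements `x` (scaled matrix) and `fit_stats`.
#' @export
minmax_scale <- function(x, fit_stats = NULL) {
  x <- as.matrix(x)
  if (is.null(fit_stats)) {
    fit_stats <- list(min = apply(x, 2, min), max = apply(x, 2, max))
  }
  rng <- fit_stats$max - fit_stats$min
  degenerate <- rng == 0
  if (any(degenerate)) {
    warning(sprintf("%d constant wavelength(s) mapped to 0 by Min-Max scaling",
                    sum(degenerate)))
    rng[degenerate] <- 1
  }
  scaled <- sweep(sweep(x, 2, fit_stats$min), 2, rng, "/")
  scaled[, degenerate] <- 0
  list(x = scaled, fit_stats = fit_stats)
}

#' Preprocessing specification
#'
#' Names one of the compared correction pipelines: `RAW` (no correction),
#' `SG` (Savitzky-Golay smoothing), `MSC`, `SNV`, or their first-derivative
#' compositions `SGFD`, `MSCFD`, `SNVFD` (scatter correction first, then the
#' derivative computed within the SG filter). Min-Max scaling with training
#' statistics is applied last when `minmax = TRUE`.
#'
#' @param method One of `"RAW"`, `"SG"`, `"MSC"`, `"SNV"`, `"SGFD"`,
#'   `"MSCFD"`, `"SNVFD"`.
#' @param sg_window Odd SG window in points (default 11).
#' @param sg_polyorder SG polynomial order (default 2).
#' @param minmax Apply Min-Max scaling as the final step (default `TRUE`).
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(method = c("RAW", "SG", "MSC", "SNV",
                                       "SGFD", "MSCFD", "SNVFD"),
                            sg_window = 11, sg_polyorder = 2, minmax = TRUE) {
  method <- match.arg(method)
  if (sg_window %% 2 == 0 || sg_polyorder >= sg_window) {
    stop("`sg_window` must be odd and greater than `sg_polyorder`")
  }
  structure(list(method = method, sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 minmax = isTRUE(minmax)),
            class = "preprocess_spec")
}

#' All seven compared preprocessing specifications
#'
#' @inheritParams preprocess_spec
#' @return Named list of [preprocess_spec()] objects.
#' @export
all_preprocess_specs <- function(sg_window = 11, sg_polyorder = 2,
                                 minmax = TRUE) {
  methods <- c("RAW", "SG", "MSC", "SNV", "SGFD", "MSCFD", "SNVFD")
  stats::setNames(lapply(methods, preprocess_spec, sg_window = sg_window,
                         sg_polyorder = sg_polyorder, minmax = minmax),
                  methods)
}

#' Apply a preprocessing pipeline
#'
#' Applies the operators named by `spec` in fixed order: scatter correction
#' (MSC or SNV) or SG smoothing first, then the first derivative for the
#' `*FD` methods, then Min-Max scaling. All data-dependent statistics (MSC
#' reference, Min-Max column ranges) are learned from the input when
#' `fitted_state` is omitted (a training call) and reused verbatim when it is
#' supplied (transforming held-out spectra), so no held-out information leaks
#' into the fit.
#'
#' @param spectra A [spectra_set()] in absorbance units.
#' @param spec A [preprocess_spec()].
#' @param fitted_state Optional state returned by a previous (training) call.
#' @return List with elements `spectra` (transformed [spectra_set()]) and
#'   `fitted_state` (list recording method, parameters, MSC reference and
#'   Min-Max statistics).
#' @export
apply_pipeline <- function(spectra, spec, fitted_state = NULL) {
  stopifnot(inherits(spectra, "spectra_set"), inherits(spec, "preprocess_spec"))
  if (spectra$unit != "absorbance") {
    stop("pipeline expects absorbance; convert with reflectance_to_absorbance()")
  }
  fitting <- is.null(fitted_state)
  if (!fitting && !identical(fitted_state$spec, unclass(spec))) {
    stop("fitted_state was produced under a different preprocessing spec")
  }
  x <- spectra$absorbance
  spacing <- mean(diff(spectra$wavelengths))
  state <- if (fitting) list(spec = unclass(spec)) else fitted_state

  stage <- function(expr, name) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' (%s): %s", name, spec$method,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # SGFD is a single SG derivative filter (smoothing and differentiation in
  # one local fit), so its first stage is the identity.
  x <- stage(switch(spec$method,
    RAW = ,
    SGFD = x,
    SG = savgol(x, spec$sg_window, spec$sg_polyorder, deriv = 0,
                spacing = spacing),
    MSC = ,
    MSCFD = {
      out <- msc(x, reference = if (fitting) NULL else state$msc_reference)
      if (fitting) state$msc_reference <- attr(out, "reference")
      attr(out, "reference") <- NULL
      out
    },
    SNV = ,
    SNVFD = snv(x)
  ), "scatter-correction")

  if (endsWith(spec$method, "FD")) {
    x <- stage(savgol(x, spec$sg_window, spec$sg_polyorder, deriv = 1,
                      spacing = spacing), "first-derivative")
  }

  if (spec$minmax) {
    res <- stage(minmax_scale(x, fit_stats = state$minmax), "min-max")
    x <- res$x
    if (fitting) state$minmax <- res$fit_stats
  }

  list(
    spectra = spectra_set(spectra$wavelengths, x, spectra$meta),
    fitted_state = state
  )
}
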