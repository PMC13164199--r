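#' Spectral generator configuration
#'
#' Parameterizes the Beer-Lambert-style mixture model used to emulate NIR
#' diffuse-reflectance absorbance spectra of stored seed samples. Each latent
#' chemical component contributes a set of Gaussian absorption bands whose
#' shared amplitude follows a smooth trajectory of storage months; per-spectrum
#' multiplicative/additive scatter and Gaussian noise are added on top.
#'
#' Two instrument grids are emulated: short-wave 900-1700 nm (228 points) and
#' long-wave 1300-2500 nm (257 points). The oxidation-product component is
#' placed inside 1300-1500 and 1800-2000 nm, so the long-wave grid carries both
#' oxidation bands while the short-wave grid sees only the first -- the
#' long-wave range is by construction the more informative one for
#' deterioration, mirroring where lipid-oxidation combination bands fall.
#'
#' @param range Which instrument to emulate: `"1300-2500"` (257 points) or
#'   `"900-1700"` (228 points).
#' @param components Optional list overriding the default latent components.
#'   Each element: `list(name=, bands=matrix(center, width, amplitude),
#'   traj=function(months, processed) scalar)`. The default set comprises a
#'   carbohydrate/protein background, water, a lipid substrate that decays
#'   with storage, oxidation products that rise with storage, and a
#'   processing component absent from the raw sample.
#' @param scatter_slope_sd SD of the per-spectrum multiplicative scatter slope.
#' @param scatter_offset_sd SD of the per-spectrum additive scatter offset
#'   (absorbance units).
#' @param noise_sd SD of additive Gaussian noise (absorbance units).
#' @param emit `"absorbance"` (default) or `"reflectance"` (`R = 10^-a`) to
#'   exercise the log10(1/R) conversion step.
#'
#' @return An object of class `spectral_config`.
#' @export
spectral_config <- function(range = c("1300-2500", "900-1700"),
                            components = NULL,
                            scatter_slope_sd = 0.02,
                            scatter_offset_sd = 0.01,
                            noise_sd = 0.002,
                            emit = c("absorbance", "reflectance")) {
  range <- match.arg(range)
  emit <- match.arg(emit)
  grid <- switch(range,
    "900-1700"  = seq(900, 1700, length.out = 228),
    "1300-2500" = seq(1300, 2500, length.out = 257))
  if (is.null(components)) components <- default_components()
  for (cmp in components) {
    b <- cmp$bands
    if (!is.matrix(b) || ncol(b) != 3 || any(b[, 2] <= 0) || any(b[, 3] <= 0)) {
      stop("each component needs a bands matrix with positive widths and amplitudes")
    }
    if (!is.function(cmp$traj)) stop("each component needs a trajectory function")
  }
  if (scatter_slope_sd < 0 || scatter_offset_sd < 0 || noise_sd < 0) {
    stop("scatter and noise SDs must be non-negative")
  }
  # the oxidation trajectory must not decrease with storage time
  ox <- Filter(function(cmp) identical(cmp$name, "oxidation"), components)
  if (length(ox) == 1) {
    m <- seq(0, 60, by = 1)
    v <- vapply(m, function(mm) ox[[1]]$traj(mm, TRUE), numeric(1))
    if (any(diff(v) < -1e-12)) {
      stop("oxidation trajectory must be monotone nondecreasing in months")
    }
  }
  structure(
    list(range = range, wavelength_grid = grid, components = components,
         scatter_slope_sd = scatter_slope_sd,
         scatter_offset_sd = scatter_offset_sd,
         noise_sd = noise_sd, emit = emit),
    class = "spectral_config"
  )
}

# Default latent components. Band centers in nm, widths as Gaussian sigmas,
# amplitudes in absorbance units. Trajectories are dimensionless multipliers
# of storage months (processed samples) with a separate raw-sample level.
default_components <- function() {
  list(
    list(
      name = "background",  # carbohydrate/protein C-H overtones
      bands = cbind(center = c(1000, 1200, 1700, 2100, 2300),
                    width  = c(60, 55, 70, 80, 70),
                    amplitude = c(0.25, 0.30, 0.35, 0.40, 0.38)),
      traj = function(months, processed) 1
    ),
    list(
      name = "water",       # O-H combination bands
      bands = cbind(center = c(1450, 1940),
                    width  = c(55, 60),
                    amplitude = c(0.45, 0.55)),
      traj = function(months, processed) 1
    ),
    list(
      name = "lipid",       # intact lipid substrate, consumed by oxidation
      bands = cbind(center = c(1210, 1720, 2310),
                    width  = c(35, 40, 45),
                    amplitude = c(0.18, 0.22, 0.20)),
      traj = function(months, processed) {
        # only a few percent of the lipid pool oxidizes over storage, so the
        # substrate bands shrink slowly relative to the oxidation-band growth
        base <- if (processed) 1 else 1.08
        base * exp(-months / 400)
      }
    ),
    list(
      name = "oxidation",   # lipid oxidation products (C-H / O-H / C=O)
      bands = cbind(center = c(1410, 1880),
                    width  = c(38, 42),
                    amplitude = c(0.10, 0.14)),
      traj = function(months, processed) {
        if (!processed) return(0)
        0.15 + 0.85 / (1 + exp(-(months - 18) / 9))
      }
    ),
    list(
      name = "processing",  # roasting products present only after processing
      bands = cbind(center = c(1150, 1680, 2220),
                    width  = c(45, 40, 50),
                    amplitude = c(0.06, 0.08, 0.07)),
      traj = function(months, processed) {
        if (!processed) return(0)
        exp(-months / 200)
      }
    )
  )
}

# Clean mixture spectrum for one sample on a grid.
clean_spectrum <- function(config, months, processed) {
  wl <- config$wavelength_grid
  a <- numeric(length(wl))
  for (cmp in config$components) {
    w <- cmp$traj(months, processed)
    if (w == 0) next
    b <- cmp$bands
    for (i in seq_len(nrow(b))) {
      a <- a + w * b[i, 3] * exp(-(wl - b[i, 1])^2 / (2 * b[i, 2]^2))
    }
  }
  a
}

#' Generate synthetic NIR spectra
#'
#' Emits one spectrum per (sample, subsample, scan) of the design: the clean
#' component mixture for the sample's storage state, distorted by a
#' per-spectrum multiplicative scatter slope `(1 + s)`, an additive offset,
#' and Gaussian noise. Deterministic given `design$seed`.
#'
#' @param design A [study_design()].
#' @param config A [spectral_config()].
#' @return A [spectra_set()] with `n_samples * n_subsamples *
#'   n_scans_per_subsample` rows.
#' @examples
#' s <- generate_spectra(study_design(), spectral_config("900-1700"))
#' dim(s)  # 350 x 228
#' @export
generate_spectra <- function(design, config) {
  stopifnot(inherits(design, "study_design"), inherits(config, "spectral_config"))
  n_samp <- length(design$sample_labels)
  n_rep <- design$n_subsamples * design$n_scans_per_subsample
  p <- length(config$wavelength_grid)

  clean <- matrix(0, n_samp, p)
  for (i in seq_len(n_samp)) {
    clean[i, ] <- clean_spectrum(config, design$storage_months[i],
                                 design$processed[i])
  }

  n <- n_samp * n_rep
  abs_mat <- matrix(0, n, p)
  meta <- data.frame(
    sample = rep(design$sample_labels, each = n_rep),
    processed = rep(design$processed, each = n_rep),
    months = rep(design$storage_months, each = n_rep),
    subsample = rep(rep(seq_len(design$n_subsamples),
                        each = design$n_scans_per_subsample), n_samp),
    scan = rep(seq_len(design$n_scans_per_subsample),
               n_samp * design$n_subsamples),
    stringsAsFactors = FALSE
  )

  with_local_seed(design$seed, {
    slope <- stats::rnorm(n, 0, config$scatter_slope_sd)
    offset <- stats::rnorm(n, 0, config$scatter_offset_sd)
    noise <- matrix(stats::rnorm(n * p, 0, config$noise_sd), n, p)
    for (r in seq_len(n)) {
      samp_i <- (r - 1L) %/% n_rep + 1L
      abs_mat[r, ] <- (1 + slope[r]) * clean[samp_i, ] + offset[r] + noise[r, ]
    }
  })

  if (config$emit == "reflectance") {
    spectra_set(config$wavelength_grid, 10^(-abs_mat), meta,
                unit = "reflectance")
  } else {
    spectra_set(config$wavelength_grid, abs_mat, meta)
  }
}
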