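test_that("study design encodes the storage layout and validates inputs", {
  d <- study_design()
  expect_identical(d$sample_labels, c("S", "P2", "P4", "P12", "P29", "P46", "P56"))
  expect_identical(d$processed, c(FALSE, rep(TRUE, 6)))
  expect_equal(d$n_subsamples * d$n_scans_per_subsample, 50)
  expect_error(study_design(storage_months = c(4, 2)), "increasing")
  expect_error(study_design(n_subsamples = 0), "positive integer")
})

test_that("spectra generator emits one spectrum per (sample, subsample, scan)", {
  d <- study_design(seed = 3)
  s <- generate_spectra(d, spectral_config("900-1700"))
  expect_equal(dim(s), c(7 * 50, 228))
  expect_equal(nrow(s$meta), 350)
  expect_equal(as.vector(table(s$meta$sample)[d$sample_labels]), rep(50L, 7))
  lw <- generate_spectra(d, spectral_config("1300-2500"))
  expect_equal(dim(lw), c(350, 257))
})

test_that("spectra generation is deterministic and noise-free mode is exact", {
  d <- study_design(seed = 7)
  cfg <- spectral_config("1300-2500")
  expect_identical(generate_spectra(d, cfg), generate_spectra(d, cfg))

  # zero noise/scatter: every spectrum equals the exact band mixture, so all
  # spectra of one sample are identical and differencing two samples
  # isolates the trajectory difference
  s0 <- generate_spectra(d, noiseless_spectral_config())
  p2 <- s0$absorbance[s0$meta$sample == "P2", ]
  expect_equal(max(apply(p2, 2, function(col) diff(range(col)))), 0)
  p56 <- s0$absorbance[s0$meta$sample == "P56", ][1, ]
  diff_obs <- p56 - p2[1, ]
  # the sample difference must be nonzero only through month-dependent
  # components (oxidation up, lipid/processing down)
  expect_gt(max(abs(diff_obs)), 0.01)

  # constant trajectories degenerate to identical spectra across samples
  flat <- spectral_config("1300-2500",
    components = list(list(name = "background",
                           bands = cbind(1500, 100, 0.5),
                           traj = function(m, p) 1)),
    scatter_slope_sd = 0, scatter_offset_sd = 0, noise_sd = 0)
  sf <- generate_spectra(d, flat)
  expect_equal(max(sf$absorbance) - min(sf$absorbance) -
                 (max(sf$absorbance[1, ]) - min(sf$absorbance[1, ])), 0)
  expect_equal(unname(apply(sf$absorbance, 2, stats::sd)),
               rep(0, ncol(sf$absorbance)))
})

test_that("spectral config rejects invalid settings", {
  expect_error(spectral_config("1300-2500", scatter_slope_sd = -1),
               "non-negative")
  bad_ox <- list(list(name = "oxidation", bands = cbind(1900, 40, 0.1),
                      traj = function(m, p) -m))
  expect_error(spectral_config("1300-2500", components = bad_ox),
               "monotone nondecreasing")
  expect_error(spectral_config("1300-2500",
    components = list(list(name = "x", bands = cbind(1500, -10, 1),
                           traj = function(m, p) 1))),
    "positive widths")
})

test_that("reflectance emission mode round-trips through log10(1/R)", {
  d <- small_design()
  ab <- generate_spectra(d, noiseless_spectral_config())
  cfg_r <- spectral_config("1300-2500", scatter_slope_sd = 0,
                           scatter_offset_sd = 0, noise_sd = 0,
                           emit = "reflectance")
  rf <- generate_spectra(d, cfg_r)
  expect_identical(rf$unit, "reflectance")
  expect_equal(reflectance_to_absorbance(rf$absorbance), ab$absorbance,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("peak table has the 74-compound census plus internal standard", {
  d <- study_design(seed = 5)
  pt <- generate_peak_table(d, volatile_config())
  expect_equal(ncol(pt$volumes), 7 * 3)
  non_is <- pt$compounds$class != "internal_standard"
  expect_equal(length(unique(pt$compounds$cas[non_is])), 74)
  expect_true("2-octanol-D4 (IS)" %in% pt$compounds$compound)
  expect_true(all(pt$volumes > 0))
  expect_identical(generate_peak_table(d, volatile_config()), pt)
  expect_error(volatile_config(class_counts = c(aldehydes = 10, other = 10)),
               "sum to 74")
})

test_that("noise-free replicates are exactly equal and trends are monotone", {
  d <- study_design(seed = 11)
  pt <- generate_peak_table(d, noiseless_volatile_config())
  for (s in c("S", "P12", "P56")) {
    cols <- which(pt$col_meta$sample == s)
    expect_equal(pt$volumes[, cols[1]], pt$volumes[, cols[2]])
    expect_equal(pt$volumes[, cols[1]], pt$volumes[, cols[3]])
  }
  # every rise-family (aldehyde) monomer strictly increases P2 -> P56
  proc <- d$sample_labels[d$processed]
  ald <- which(pt$compounds$class == "aldehydes" & pt$compounds$form == "M")
  for (i in ald) {
    means <- vapply(proc, function(s) {
      mean(pt$volumes[i, pt$col_meta$sample == s])
    }, numeric(1))
    expect_false(is.unsorted(means, strictly = TRUE))
  }
})

test_that("monomer/dimer pairs share one trend up to a fixed ratio", {
  pt <- generate_peak_table(study_design(seed = 13), noiseless_volatile_config())
  dimers <- which(pt$compounds$form == "D")
  expect_gt(length(dimers), 0)
  for (i in dimers) {
    mono <- which(pt$compounds$cas == pt$compounds$cas[i] &
                    pt$compounds$form == "M")
    ratio <- pt$volumes[i, ] / pt$volumes[mono, ]
    expect_equal(diff(range(ratio)), 0, tolerance = 1e-12)
    expect_true(all(ratio > 0 & ratio < 1))
  }
})

test_that("internal-standard division cancels the injection factor exactly", {
  cfg <- volatile_config(replicate_cv = 0, injection_effect_sd = 0.3)
  pt <- generate_peak_table(study_design(seed = 17), cfg)
  is_row <- which(pt$compounds$compound == pt$internal_standard)
  norm <- sweep(pt$volumes[-is_row, ], 2, pt$volumes[is_row, ], "/")
  # after cancellation all replicates of one sample are identical
  for (s in unique(pt$col_meta$sample)) {
    cols <- which(pt$col_meta$sample == s)
    expect_equal(norm[, cols[1]], norm[, cols[2]], tolerance = 1e-12)
  }
})

test_that("ground-truth index is monotone with a ~6 unit span", {
  d <- study_design()
  idx <- true_index(d)
  expect_equal(names(idx), c("P2", "P4", "P12", "P29", "P46", "P56"))
  expect_false(is.unsorted(idx, strictly = TRUE))
  expect_equal(abs(idx[["P56"]] - idx[["P2"]]), 6)
  # equal months would give equal index values (affine map of months)
  m <- d$storage_months[d$processed]
  expect_equal(unname(idx), 6 * (m - min(m)) / diff(range(m)))
})

test_that("spectra and peak tables round-trip through their CSV formats", {
  d <- small_design()
  s <- generate_spectra(d, spectral_config("900-1700"))
  f <- tempfile(fileext = ".csv")
  write_spectra_csv(s, f)
  s2 <- read_spectra_csv(f)
  expect_equal(s2$absorbance, s$absorbance, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(s2$meta$sample, s$meta$sample)

  pt <- generate_peak_table(d, volatile_config())
  f2 <- tempfile(fileext = ".csv")
  write_peak_table_csv(pt, f2)
  pt2 <- read_peak_table_csv(f2, internal_standard = pt$internal_standard)
  expect_equal(pt2$volumes, pt$volumes, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(pt2$compounds$cas, pt$compounds$cas)
  unlink(c(f, f2))
})
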