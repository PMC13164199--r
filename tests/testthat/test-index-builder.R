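test_that("internal-standard normalization cancels per-replicate factors", {
  d <- small_design()
  pt <- generate_peak_table(d, noiseless_volatile_config())
  # doubling every volume of one replicate (injection effect) must vanish
  pt2 <- pt
  pt2$volumes[, 4] <- pt2$volumes[, 4] * 2
  n1 <- normalize_to_internal_standard(pt)
  n2 <- normalize_to_internal_standard(pt2)
  expect_equal(n1$volumes, n2$volumes, tolerance = 1e-12)
  expect_true(is.na(n1$internal_standard))
  expect_false(any(n1$compounds$class == "internal_standard"))

  # internal standard exactly 1 everywhere: table unchanged except row removal
  pt3 <- pt
  is_row <- which(pt3$compounds$compound == pt3$internal_standard)
  pt3$volumes[is_row, ] <- 1
  n3 <- normalize_to_internal_standard(pt3)
  expect_equal(n3$volumes, pt3$volumes[-is_row, ], tolerance = 1e-12)

  # missing/zero internal standard is a hard error naming the replicate
  pt4 <- pt
  pt4$volumes[is_row, 2] <- NA
  expect_error(normalize_to_internal_standard(pt4), "replicate")
  expect_error(normalize_to_internal_standard(n1), "already normalized")
})

test_that("normalization shrinks between-replicate variability", {
  d <- study_design(seed = 21)
  pt <- generate_peak_table(d, volatile_config(replicate_cv = 0.03,
                                               injection_effect_sd = 0.25))
  nt <- normalize_to_internal_standard(pt)
  rise <- which(pt$compounds$class == "aldehydes" & pt$compounds$form == "M")
  cv_of <- function(vols, i) {
    mean(tapply(vols[i, ], pt$col_meta$sample, function(v) sd(v) / mean(v)))
  }
  raw_rows <- match(nt$compounds$compound, pt$compounds$compound)
  for (i in rise) {
    j <- which(raw_rows == i)
    expect_lt(cv_of(nt$volumes, j), cv_of(pt$volumes, i))
  }
})

test_that("form deduplication keeps the more stable ion and logs consistency", {
  # constructed table: M stable and intense, D weak and noisy -> keep M
  cmp <- data.frame(compound = c("acid-M", "acid-D"),
                    cas = c("C1", "C1"), form = c("M", "D"),
                    class = c("acids", "acids"))
  meta <- data.frame(sample = rep(c("P2", "P56"), each = 3),
                     replicate = rep(1:3, 2))
  m_vals <- c(100, 100, 100, 200, 200, 200) * rep(c(0.95, 1, 1.05), 2)
  d_vals <- c(40, 40, 40, 80, 80, 80) * rep(c(0.8, 1, 1.2), 2)
  pt <- peak_table(cmp, rbind(m_vals, d_vals), meta)
  out <- deduplicate_forms(pt)
  expect_identical(out$compounds$compound, "acid-M")
  log <- attr(out, "dedup_log")
  expect_identical(log$discarded, "acid-D")
  expect_equal(log$profile_spearman, 1)

  # identical M and D values: tie broken toward the monomer
  pt_tie <- peak_table(cmp, rbind(m_vals, m_vals), meta)
  expect_identical(deduplicate_forms(pt_tie)$compounds$compound, "acid-M")
})

test_that("deduplicated synthetic tables have one row per CAS with rho = 1", {
  d <- small_design()
  nt <- normalize_to_internal_standard(
    generate_peak_table(d, noiseless_volatile_config()))
  out <- deduplicate_forms(nt)
  expect_false(any(duplicated(out$compounds$cas)))
  expect_equal(nrow(out$volumes), 74)
  log <- attr(out, "dedup_log")
  expect_gt(nrow(log), 0)
  # M and D generated from one trend with a fixed ratio: profiles correlate
  # perfectly (flat processing-free classes give rank ties -> NA; exclude)
  rho <- log$profile_spearman[!is.na(log$profile_spearman)]
  expect_equal(rho, rep(1, length(rho)), tolerance = 1e-12)
})

test_that("composite deterioration index rank-orders storage months", {
  d <- study_design(seed = 1)
  nt <- deduplicate_forms(normalize_to_internal_standard(
    generate_peak_table(d, volatile_config())))
  proc <- d$sample_labels[d$processed]
  months <- stats::setNames(d$storage_months[d$processed], proc)
  mat <- t(nt$volumes[, nt$col_meta$sample %in% proc])
  mk <- screen_markers(mat, nt$col_meta$sample[nt$col_meta$sample %in% proc] %in%
                         c("P46", "P56"),
                       threshold = 1, k_folds = 3, seed = 1)
  idx <- build_index(nt, months, mk$compound, kind = "deterioration")
  rho <- stats::cor(idx$values[proc], months, method = "spearman")
  expect_equal(rho, 1.0)
  expect_identical(idx$kind, "deterioration")

  # orientation convention: positively correlated with the response
  expect_gt(stats::cor(idx$values, months), 0)
})

test_that("index construction guards and symmetries hold", {
  d <- small_design()
  nt <- deduplicate_forms(normalize_to_internal_standard(
    generate_peak_table(d, noiseless_volatile_config())))
  months <- stats::setNames(d$storage_months[d$processed],
                            d$sample_labels[d$processed])
  markers <- nt$compounds$compound[1:10]

  expect_error(build_index(nt, stats::setNames(rep(1, 6), names(months)),
                           markers), "constant response")
  expect_error(build_index(nt, months, character(0)), "empty")
  expect_error(build_index(nt, months[1:2], markers), "at least 3")
  expect_error(build_index(nt, months, c("nope", markers)), "absent")

  idx <- build_index(nt, months, markers)
  # negating all marker volumes only reflects the latent direction; the
  # orientation convention absorbs it
  neg <- nt
  neg$volumes <- -neg$volumes
  class(neg) <- "peak_table"  # bypass positivity check for the symmetry probe
  idx_neg <- build_index(neg, months, markers)
  expect_equal(idx_neg$values, idx$values, tolerance = 1e-10)
})

test_that("index projection is consistent with training scores", {
  d <- study_design(seed = 2)
  nt <- deduplicate_forms(normalize_to_internal_standard(
    generate_peak_table(d, volatile_config())))
  months <- stats::setNames(d$storage_months[d$processed],
                            d$sample_labels[d$processed])
  idx <- build_index(nt, months, nt$compounds$compound[1:20])
  proj <- project_index(idx, nt)
  expect_equal(proj[names(idx$values)], idx$values, tolerance = 1e-10)

  # a sample sitting exactly at the training marker means scores 0
  M <- colMeans(do.call(rbind, lapply(names(months), function(s) {
    rowMeans(nt$volumes[match(idx$markers, nt$compounds$compound),
                        nt$col_meta$sample == s, drop = FALSE])
  })))
  mean_table <- peak_table(
    nt$compounds[match(idx$markers, nt$compounds$compound), ],
    matrix(M, ncol = 1, dimnames = list(idx$markers, NULL)),
    data.frame(sample = "center", replicate = 1))
  expect_equal(unname(project_index(idx, mean_table)), 0, tolerance = 1e-10)

  # missing marker columns are a schema error
  short <- peak_table(nt$compounds[1:5, ], nt$volumes[1:5, , drop = FALSE],
                      nt$col_meta)
  expect_error(project_index(idx, short), "absent")
})
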