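test_that("PLS1 recovers an exact single-factor relationship", {
  # noise columns residualized against y so the single latent direction
  # carries all predictor-response covariance
  withr::with_seed(1, {
    x1 <- rnorm(20)
    N <- matrix(rnorm(20 * 4), 20, 4)
  })
  y <- 3 * x1
  yc <- y - mean(y)
  N <- apply(N, 2, function(col) {
    col - mean(col) - sum((col - mean(col)) * yc) / sum(yc^2) * yc
  })
  m <- fit_pls1(cbind(x1, N), y, n_lv = 1)
  r2 <- 1 - sum((y - predict(m, cbind(x1, N)))^2) / sum((y - mean(y))^2)
  expect_gt(r2, 1 - 1e-8)
})

test_that("full-rank PLS1 at maximal components equals least squares", {
  for (seed in 1:3) {
    withr::with_seed(seed, {
      X <- matrix(rnorm(150), 30, 5)
      y <- rnorm(30)
    })
    m <- fit_pls1(X, y, n_lv = 5)
    ols <- stats::lm.fit(cbind(1, X), y)
    expect_lt(max(abs(predict(m, X) - ols$fitted.values)), 1e-8)
  }
})

test_that("duplicated predictor columns leave predictions unchanged", {
  withr::with_seed(2, {
    X <- matrix(rnorm(60), 20, 3)
    y <- X %*% c(1, -2, 0.5) + rnorm(20, 0, 0.1)
  })
  # at the full rank of the column space both models converge to the same
  # least-squares fit; the duplicated column only splits coefficient mass
  m1 <- fit_pls1(X, y, n_lv = 3)
  m2 <- fit_pls1(cbind(X, X[, 1]), y, n_lv = 3)
  expect_equal(predict(m2, cbind(X, X[, 1])), predict(m1, X),
               tolerance = 1e-8)
  expect_equal(m2$coefficients[1] + m2$coefficients[4], m1$coefficients[1],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("scores are orthogonal and coefficients reproduce score predictions", {
  for (seed in 1:4) {
    withr::with_seed(seed, {
      X <- matrix(rnorm(40 * 12), 40, 12)
      y <- rnorm(40)
    })
    m <- fit_pls1(X, y, n_lv = 6)
    G <- crossprod(m$T)
    off <- max(abs(G - diag(diag(G)))) / max(diag(G))
    expect_lt(off, 1e-8)
    # prediction via coefficients equals prediction via score projection
    via_scores <- drop(pls_scores(m, X) %*% m$q) + m$y_mean
    expect_lt(max(abs(via_scores - predict(m, X))), 1e-10)
  }
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(30), 10, 3)
  expect_error(fit_pls1(X, rep(1, 10), n_lv = 1), "zero variance")
  expect_error(fit_pls1(X, rnorm(10), n_lv = 4), "n_lv must be in")
  expect_error(fit_pls1(X[1:2, ], rnorm(2), n_lv = 1), "at least 3")
})

test_that("metrics follow their definitions and algebraic identities", {
  y <- c(1, 2, 3, 4, 5)
  m <- compute_metrics(y, y + c(0.5, -0.5, 0.5, -0.5, 0), context = "test")
  expect_equal(m$rmse, sqrt(mean(c(0.25, 0.25, 0.25, 0.25, 0))))
  expect_equal(m$rpd, sd(y) / m$rmse)
  # sd 2, rmse 0.5 -> RPD 4 (definitional)
  y2 <- c(0, 2, 4)  # sd = 2
  pred <- y2 + c(0.5, -0.5, 0.5)
  m2 <- compute_metrics(y2, pred)
  expect_equal(m2$rpd, 2 / sqrt(mean(c(0.25, 0.25, 0.25))))
  # closed-form identity RPD = sqrt(n/(n-1)) / sqrt(1 - R2)
  withr::with_seed(3, {
    yt <- rnorm(50); yp <- yt + rnorm(50, 0, 0.4)
  })
  mm <- compute_metrics(yt, yp)
  expect_equal(mm$rpd, sqrt(50 / 49) / sqrt(1 - mm$r2), tolerance = 1e-10)
  # perfect prediction: R2 = 1, RMSE = 0, RPD guarded (infinite, no error)
  mp <- compute_metrics(yt, yt)
  expect_equal(mp$r2, 1)
  expect_equal(mp$rmse, 0)
  expect_true(is.infinite(mp$rpd))
  expect_error(compute_metrics(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("cross-validated LV selection is parsimonious and honors the grid", {
  # rank-1 predictor block: every LV count fits identically, so the
  # parsimony tie-break must pick a single component
  withr::with_seed(5, x1 <- rnorm(40))
  X1 <- outer(x1, c(1, -0.5, 2, 0.3))
  cv <- cross_validate_lv(X1, 2 * x1, lv_grid = 1:4, k = 5, seed = 1)
  expect_equal(cv$best_lv, 1)

  # the grid upper bound holds even though p = 15 > 10
  withr::with_seed(5, X <- matrix(rnorm(40 * 15), 40, 15))
  y <- drop(X %*% c(2, rep(0, 14)))
  cvg <- cross_validate_lv(X, y, lv_grid = 1:10, k = 5, seed = 1)
  expect_lte(max(cvg$lv_grid), 10)
  expect_lte(cvg$best_lv, 10)

  # pure-noise response: no LV count achieves positive pooled Rcv2
  withr::with_seed(6, yn <- rnorm(40))
  cvn <- cross_validate_lv(X, yn, lv_grid = 1:10, k = 5, seed = 1)
  r2s <- vapply(cvn$cv_metrics, `[[`, numeric(1), "r2")
  expect_true(all(r2s <= 0.05))

  # deterministic given the same stratification labels and seed
  strata <- rep(letters[1:4], each = 10)
  a <- cross_validate_lv(X, y, k = 4, strata = strata, seed = 9)
  b <- cross_validate_lv(X, y, k = 4, strata = strata, seed = 9)
  expect_identical(a$best_lv, b$best_lv)
  expect_equal(a$cv_pred, b$cv_pred)
})

test_that("VIP scores satisfy the normalization identity and locate signal", {
  # single informative variable among inert ones: VIP = sqrt(p) for it
  X <- cbind(sig = c(-2, -1, 0, 1, 2, 3), matrix(1, 6, 2))
  y <- 2 * X[, 1]
  m <- fit_pls1(X, y, n_lv = 1)
  v <- vip(m)
  expect_equal(unname(v[1]), sqrt(3), tolerance = 1e-10)
  expect_equal(unname(v[2:3]), c(0, 0), tolerance = 1e-10)

  # all variables identical: symmetry forces VIP = 1 everywhere
  Xs <- matrix(rep(c(1, 2, 3, 5, 8), 4), 5, 4)
  ms <- fit_pls1(Xs, c(1, 2, 3, 5, 8), n_lv = 1)
  expect_equal(unname(vip(ms)), rep(1, 4), tolerance = 1e-10)

  # mean squared VIP = 1 for every fitted model
  for (seed in 1:5) {
    withr::with_seed(seed, {
      X <- matrix(rnorm(30 * 8), 30, 8)
      y <- rnorm(30)
    })
    m <- fit_pls1(X, y, n_lv = sample(1:5, 1))
    expect_equal(mean(vip(m)^2), 1, tolerance = 1e-8)
  }
})

test_that("PCA scores match the covariance-eigendecomposition oracle", {
  # rank-1 matrix: first component explains everything
  r1 <- outer(1:6, c(2, -1, 3))
  p1 <- pca_scores(r1, 1)
  expect_equal(unname(p1$explained_variance_ratio), 1)

  withr::with_seed(7, A <- matrix(rnorm(25 * 10), 25, 10))
  pr <- pca_scores(A, 4)
  ev <- eigen(stats::cov(A), symmetric = TRUE)$values
  expect_equal(unname(pr$explained_variance_ratio), ev[1:4] / sum(ev),
               tolerance = 1e-10)
  expect_lte(sum(pr$explained_variance_ratio), 1 + 1e-12)
  # deterministic: repeated calls agree exactly
  expect_identical(pca_scores(A, 4), pr)
  expect_error(pca_scores(A, 30), "n_components")
})

test_that("PLS models round-trip through JSON serialization", {
  withr::with_seed(8, {
    X <- matrix(rnorm(60), 20, 3)
    y <- rnorm(20)
  })
  m <- fit_pls1(X, y, n_lv = 2, scale_x = TRUE)
  f <- tempfile(fileext = ".json")
  save_pls_model(m, f)
  m2 <- load_pls_model(f)
  expect_equal(m2$coefficients, unname(m$coefficients))
  expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-12)
  unlink(f)
})
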