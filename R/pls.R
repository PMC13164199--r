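#' NIPALS partial least squares regression (single response)
#'
#' Fits a PLS1 model by NIPALS deflation on centered (optionally
#' unit-variance-scaled) data. Latent variables maximize predictor-response
#' covariance; the regression coefficient vector on the original scale is
#' recovered as `B = W (P'W)^-1 q`, rescaled by the centering/scaling
#' parameters. Deterministic: PLS1 needs no random initialization.
#'
#' @param X Predictor matrix, samples x variables.
#' @param y Numeric response vector.
#' @param n_lv Number of latent variables, `<= min(n - 1, p)`.
#' @param scale_x Divide each predictor column by its SD before fitting.
#'   Spectra are usually centered only (derivative magnitudes are
#'   meaningful); peak-volume matrices spanning decades are usually scaled.
#' @return An object of class `pls_model` with weights `W`, loadings `P`,
#'   y-loadings `q`, scores `T`, original-scale coefficients `coefficients`
#'   and `intercept`, the centering/scaling parameters, and per-component
#'   explained y-variance `ssy`.
#' @examples
#' X <- matrix(rnorm(60), 20, 3); y <- X[, 1] * 2 + rnorm(20, 0, 0.1)
#' m <- fit_pls1(X, y, n_lv = 2)
#' cor(predict(m, X), y)
#' @export
fit_pls1 <- function(X, y, n_lv, scale_x = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 3) stop("PLS1 needs at least 3 samples")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (any(!is.finite(X)) || any(!is.finite(y))) stop("non-finite inputs")
  if (stats::sd(y) == 0) stop("degenerate response: y has zero variance")
  max_lv <- min(n - 1L, p)
  if (n_lv < 1 || n_lv > max_lv) {
    stop(sprintf("n_lv must be in 1..%d (n-1, p bound)", max_lv))
  }

  x_mean <- colMeans(X)
  x_scale <- if (scale_x) {
    s <- apply(X, 2, stats::sd)
    s[s == 0] <- 1
    s
  } else rep(1, p)
  y_mean <- mean(y)

  Xc <- sweep(sweep(X, 2, x_mean), 2, x_scale, "/")
  yc <- y - y_mean

  W <- matrix(0, p, n_lv)
  P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  ssy <- numeric(n_lv)

  Xd <- Xc
  yd <- yc
  actual <- 0L
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(Xd, yd))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-14) break  # residual X carries no covariance with y
    w <- w / wn
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    if (tt < 1e-14) break
    p_a <- drop(crossprod(Xd, t)) / tt
    q_a <- sum(yd * t) / tt
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t; q[a] <- q_a
    ssy[a] <- q_a^2 * tt
    Xd <- Xd - tcrossprod(t, p_a)
    yd <- yd - q_a * t
    actual <- a
  }
  if (actual == 0L) stop("no predictive component could be extracted")
  if (actual < n_lv) {
    W <- W[, seq_len(actual), drop = FALSE]
    P <- P[, seq_len(actual), drop = FALSE]
    Tm <- Tm[, seq_len(actual), drop = FALSE]
    q <- q[seq_len(actual)]
    ssy <- ssy[seq_len(actual)]
  }

  # coefficients in centered/scaled space, then back to original units
  Bstar <- W %*% solve(crossprod(P, W), q)
  B <- drop(Bstar) / x_scale
  intercept <- y_mean - sum(x_mean * B)

  structure(
    list(n_lv = actual, W = W, P = P, q = q, T = Tm, ssy = ssy,
         x_mean = x_mean, x_scale = x_scale, y_mean = y_mean,
         coefficients = B, intercept = intercept, scale_x = scale_x),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("NIPALS PLS1 model: %d latent variable(s), %d predictors\n",
              x$n_lv, length(x$coefficients)))
  invisible(x)
}

#' Predict from a PLS1 model
#'
#' @param object A [fit_pls1()] model.
#' @param newdata Predictor matrix.
#' @param n_lv Optionally predict with the first `n_lv` components only.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, n_lv = object$n_lv, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$x_mean)) stop("newdata has wrong column count")
  if (n_lv == object$n_lv) {
    return(drop(X %*% object$coefficients) + object$intercept)
  }
  if (n_lv < 1 || n_lv > object$n_lv) stop("n_lv out of fitted range")
  a <- seq_len(n_lv)
  Bstar <- object$W[, a, drop = FALSE] %*%
    solve(crossprod(object$P[, a, drop = FALSE],
                    object$W[, a, drop = FALSE]), object$q[a])
  B <- drop(Bstar) / object$x_scale
  drop(X %*% B) + (object$y_mean - sum(object$x_mean * B))
}

#' Project new samples onto the latent space
#'
#' @param object A [fit_pls1()] model.
#' @param newdata Predictor matrix on the original scale.
#' @return Score matrix (samples x latent variables).
#' @export
pls_scores <- function(object, newdata) {
  X <- sweep(sweep(as.matrix(newdata), 2, object$x_mean), 2,
             object$x_scale, "/")
  # scores via the direct projection weights R = W (P'W)^-1
  R <- object$W %*% solve(crossprod(object$P, object$W))
  X %*% R
}

#' Regression performance metrics
#'
#' Computes the three calibration metrics used throughout the workflow:
#' `R2 = 1 - SS_res / SS_tot`, `RMSE = sqrt(mean((y - yhat)^2))`, and the
#' residual prediction deviation `RPD = sd(y, n-1) / RMSE` (RPD > 3 is the
#' conventional threshold for an excellent calibration).
#'
#' @param y_true Reference values (length >= 3).
#' @param y_pred Predictions, same length.
#' @param context Label recorded with the metrics: `"cv"`, `"test"` or
#'   `"train"`.
#' @return List of class `model_metrics` with `r2`, `rmse`, `rpd`, `context`.
#' @export
compute_metrics <- function(y_true, y_pred, context = c("cv", "test", "train")) {
  context <- match.arg(context)
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 3)
  sdy <- stats::sd(y_true)
  if (sdy == 0) stop("RPD undefined: y_true has zero variance")
  rmse <- sqrt(mean((y_true - y_pred)^2))
  r2 <- 1 - sum((y_true - y_pred)^2) / sum((y_true - mean(y_true))^2)
  rpd <- if (rmse == 0) Inf else sdy / rmse
  structure(list(r2 = r2, rmse = rmse, rpd = rpd, context = context),
            class = "model_metrics")
}

#' Cross-validated latent-variable selection
#'
#' Selects the number of latent variables by k-fold cross-validation over a
#' grid, maximizing the cross-validated R2 computed from pooled out-of-fold
#' predictions (stable for small folds). Folds are stratified by `strata`
#' when given, else random; ties break toward fewer components (parsimony).
#' The returned model is refit on all rows at the selected count.
#'
#' @param X Predictor matrix.
#' @param y Response vector.
#' @param lv_grid Candidate component counts (default `1:10`); entries beyond
#'   the rank bound are dropped.
#' @param k Number of folds (default 5).
#' @param strata Optional stratification labels (e.g. storage class).
#' @param seed RNG seed for the fold assignment.
#' @param scale_x Passed to [fit_pls1()].
#' @return List with `best_lv`, `model` (refit on all rows), `cv_metrics`
#'   (per-LV [compute_metrics()] results) and `cv_pred` (pooled out-of-fold
#'   predictions at `best_lv`).
#' @export
cross_validate_lv <- function(X, y, lv_grid = 1:10, k = 5, strata = NULL,
                              seed = 1L, scale_x = FALSE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (length(lv_grid) == 0) stop("lv_grid must be nonempty")
  if (k > n) stop("k exceeds the number of samples")
  if (is.null(strata)) strata <- rep("all", n)
  folds <- make_folds(strata, k, seed)

  max_feasible <- min(vapply(seq_len(k), function(f) {
    sum(folds != f) - 1L
  }, integer(1)), ncol(X))
  grid <- lv_grid[lv_grid <= max_feasible]
  if (length(grid) == 0) stop("no feasible latent-variable count in lv_grid")

  oof <- matrix(NA_real_, n, length(grid))
  for (f in seq_len(k)) {
    tr <- folds != f
    m <- fit_pls1(X[tr, , drop = FALSE], y[tr], n_lv = max(grid),
                  scale_x = scale_x)
    for (gi in seq_along(grid)) {
      lv <- min(grid[gi], m$n_lv)
      oof[!tr, gi] <- predict(m, X[!tr, , drop = FALSE], n_lv = lv)
    }
  }
  cv_metrics <- lapply(seq_along(grid), function(gi) {
    compute_metrics(y, oof[, gi], context = "cv")
  })
  r2s <- vapply(cv_metrics, `[[`, numeric(1), "r2")
  best_i <- which.max(r2s)  # which.max returns the first (fewest-LV) maximum
  best_lv <- grid[best_i]
  list(best_lv = best_lv,
       model = fit_pls1(X, y, n_lv = best_lv, scale_x = scale_x),
       lv_grid = grid,
       cv_metrics = stats::setNames(cv_metrics, paste0("lv", grid)),
       cv_pred = oof[, best_i])
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a)` where
#' `SSY_a` is the y-variance explained by component `a`. Satisfies the
#' normalization identity `mean(VIP^2) = 1`.
#'
#' @param model A [fit_pls1()] model.
#' @return Numeric vector of VIP scores (named if `X` had column names).
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  p <- nrow(model$W)
  ssy <- model$ssy
  if (sum(ssy) <= 0) stop("degenerate model: no explained y-variance")
  wnorm2 <- colSums(model$W^2)  # = 1 by construction, kept for clarity
  contrib <- sweep(model$W^2, 2, wnorm2, "/") %*% ssy
  scores <- sqrt(p * drop(contrib) / sum(ssy))
  names(scores) <- rownames(model$W)
  scores
}

#' Principal component scores
#'
#' Column-mean-centered SVD decomposition (no scaling by default, matching
#' typical peak-volume score plots) with explained-variance ratios.
#'
#' @param X Data matrix.
#' @param n_components Number of components, `<= min(n - 1, p)`.
#' @param scale. Scale columns to unit variance before decomposition.
#' @return List with `scores` (n x n_components) and
#'   `explained_variance_ratio`.
#' @export
pca_scores <- function(X, n_components, scale. = FALSE) {
  X <- as.matrix(X)
  max_c <- min(nrow(X) - 1L, ncol(X))
  if (n_components < 1 || n_components > max_c) {
    stop(sprintf("n_components must be in 1..%d", max_c))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  var_all <- pc$sdev^2
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained_variance_ratio = var_all[seq_len(n_components)] / sum(var_all))
}

#' Save / load a PLS model as JSON
#'
#' Arrays are stored row-major with shapes recorded, so models round-trip
#' bit-exactly across sessions.
#'
#' @param model A [fit_pls1()] model.
#' @param path JSON file path.
#' @return `save_pls_model` returns `path` invisibly; `load_pls_model`
#'   returns the reconstructed `pls_model`.
#' @export
save_pls_model <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  enc <- function(m) list(shape = dim(m), data = as.numeric(t(m)))
  payload <- list(
    n_lv = model$n_lv, scale_x = model$scale_x,
    W = enc(model$W), P = enc(model$P), T = enc(model$T),
    q = model$q, ssy = model$ssy,
    x_mean = model$x_mean, x_scale = model$x_scale, y_mean = model$y_mean,
    coefficients = model$coefficients, intercept = model$intercept
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_pls_model
#' @export
load_pls_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- function(e) matrix(e$data, nrow = e$shape[1], ncol = e$shape[2],
                            byrow = TRUE)
  structure(
    list(n_lv = as.integer(p$n_lv), W = dec(p$W), P = dec(p$P),
         q = as.numeric(p$q), T = dec(p$T), ssy = as.numeric(p$ssy),
         x_mean = as.numeric(p$x_mean), x_scale = as.numeric(p$x_scale),
         y_mean = p$y_mean, coefficients = as.numeric(p$coefficients),
         intercept = p$intercept, scale_x = isTRUE(p$scale_x)),
    class = "pls_model"
  )
}
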