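#' Two-class OPLS-DA
#'
#' Orthogonal partial least squares discriminant analysis: variation in `X`
#' orthogonal to the class contrast is iteratively removed (each orthogonal
#' weight is the X-loading minus its projection on the predictive direction),
#' then a single predictive PLS component is fit on the filtered matrix.
#' Reduces exactly to PLS1 on the class-coded response when `n_orth = 0`.
#'
#' Diagnostics: `r2x` (X-variance captured by predictive + orthogonal
#' components), `r2y` (class-variance explained), `q2` (cross-validated
#' predictive fraction from pooled out-of-fold residuals) and CV
#' classification accuracy at the midpoint cutoff. When `groups` is supplied
#' (e.g. replicate injections of one physical sample), folds keep all rows of
#' a group together to prevent replicate leakage.
#'
#' @param X Data matrix, observations x variables.
#' @param class_labels Two-level factor/character vector.
#' @param n_orth Number of orthogonal components; `NULL` (default) selects by
#'   incrementing while CV Q2 improves by more than 0.01, capped at 3.
#' @param k_folds CV folds (default 5, reduced to the feasible maximum).
#' @param groups Optional grouping labels for leakage-safe folding.
#' @param seed RNG seed for fold assignment.
#' @param scale_x Unit-variance scale columns (default `TRUE`; peak volumes
#'   span decades).
#' @return An object of class `oplsda_model`.
#' @export
fit_oplsda <- function(X, class_labels, n_orth = NULL, k_folds = 5,
                       groups = NULL, seed = 1L, scale_x = TRUE) {
  X <- as.matrix(X)
  cls <- as.character(class_labels)
  lev <- sort(unique(cls))
  if (length(lev) != 2) {
    stop(sprintf("OPLS-DA supports exactly two classes (got %d)", length(lev)))
  }
  if (any(table(cls) < 2)) stop("each class needs at least 2 observations")
  y <- as.numeric(cls == lev[2])  # {0,1} coding, second (sorted) level = 1

  if (is.null(n_orth)) {
    q2_prev <- oplsda_q2(X, y, cls, 0, k_folds, groups, seed, scale_x)
    n_orth <- 0L
    for (cand in 1:3) {
      q2_cand <- oplsda_q2(X, y, cls, cand, k_folds, groups, seed, scale_x)
      if (q2_cand > q2_prev + 0.01) {
        n_orth <- cand
        q2_prev <- q2_cand
      } else break
    }
  }

  core <- oplsda_core(X, y, n_orth, scale_x)
  cv <- oplsda_cv(X, y, cls, n_orth, k_folds, groups, seed, scale_x)

  structure(
    c(core,
      list(n_orth = n_orth, classes = lev,
           encoding = stats::setNames(c(0, 1), lev),
           q2 = cv$q2, accuracy = cv$accuracy, cv_pred = cv$pred,
           seed = seed, scale_x = scale_x)),
    class = "oplsda_model"
  )
}

# Deterministic decomposition at fixed n_orth (no CV).
oplsda_core <- function(X, y, n_orth, scale_x) {
  n <- nrow(X); p <- ncol(X)
  x_mean <- colMeans(X)
  x_scale <- if (scale_x) {
    s <- apply(X, 2, stats::sd); s[s == 0] <- 1; s
  } else rep(1, p)
  Xc <- sweep(sweep(X, 2, x_mean), 2, x_scale, "/")
  yc <- y - mean(y)
  ssx_tot <- sum(Xc^2)
  ssy_tot <- sum(yc^2)
  if (ssy_tot == 0) stop("degenerate class coding")

  w <- drop(crossprod(Xc, yc))
  w <- w / sqrt(sum(w^2))

  W_o <- matrix(0, p, n_orth)
  P_o <- matrix(0, p, n_orth)
  T_o <- matrix(0, n, n_orth)
  Xf <- Xc
  n_done <- 0L
  for (i in seq_len(n_orth)) {
    t <- drop(Xf %*% w)
    p_load <- drop(crossprod(Xf, t)) / sum(t^2)
    w_orth <- p_load - drop(crossprod(w, p_load)) * w
    nrm <- sqrt(sum(w_orth^2))
    if (nrm < 1e-12) break  # nothing orthogonal left to remove
    w_orth <- w_orth / nrm
    t_orth <- drop(Xf %*% w_orth)
    p_orth <- drop(crossprod(Xf, t_orth)) / sum(t_orth^2)
    W_o[, i] <- w_orth; P_o[, i] <- p_orth; T_o[, i] <- t_orth
    Xf <- Xf - tcrossprod(t_orth, p_orth)
    n_done <- i
  }
  if (n_done < n_orth) {
    W_o <- W_o[, seq_len(n_done), drop = FALSE]
    P_o <- P_o[, seq_len(n_done), drop = FALSE]
    T_o <- T_o[, seq_len(n_done), drop = FALSE]
  }

  # one predictive component on the filtered matrix
  w_p <- drop(crossprod(Xf, yc))
  w_p <- w_p / sqrt(sum(w_p^2))
  t_p <- drop(Xf %*% w_p)
  p_p <- drop(crossprod(Xf, t_p)) / sum(t_p^2)
  q_p <- sum(yc * t_p) / sum(t_p^2)

  ssx_expl <- sum(tcrossprod(t_p, p_p)^2)
  if (n_done > 0) {
    for (i in seq_len(n_done)) {
      ssx_expl <- ssx_expl + sum(tcrossprod(T_o[, i], P_o[, i])^2)
    }
  }
  resid_y <- yc - q_p * t_p
  list(
    w_pred = w_p, p_pred = p_p, q_pred = q_p, t_pred = t_p,
    W_orth = W_o, P_orth = P_o, T_orth = T_o,
    x_mean = x_mean, x_scale = x_scale, y_mean = mean(y),
    r2x = ssx_expl / ssx_tot,
    r2y = 1 - sum(resid_y^2) / ssy_tot
  )
}

# Predict the continuous class score for new rows.
oplsda_predict_core <- function(core, X) {
  Xc <- sweep(sweep(as.matrix(X), 2, core$x_mean), 2, core$x_scale, "/")
  if (ncol(core$W_orth) > 0) {
    for (i in seq_len(ncol(core$W_orth))) {
      t_o <- drop(Xc %*% core$W_orth[, i])
      Xc <- Xc - tcrossprod(t_o, core$P_orth[, i])
    }
  }
  t_p <- drop(Xc %*% core$w_pred)
  core$y_mean + core$q_pred * t_p
}

# Group-aware stratified folds: rows of one group stay together, groups are
# stratified over folds by their class.
oplsda_folds <- function(cls, groups, k, seed) {
  if (is.null(groups)) return(make_folds(cls, k, seed))
  g <- as.character(groups)
  ug <- unique(g)
  gcls <- cls[match(ug, g)]
  k_eff <- min(k, min(table(gcls)) * 2L, length(ug))
  if (k_eff < 2) stop("too few groups per class for cross-validation")
  gf <- make_folds(gcls, k_eff, seed)
  gf[match(g, ug)]
}

oplsda_cv <- function(X, y, cls, n_orth, k_folds, groups, seed, scale_x) {
  n <- nrow(X)
  k_eff <- min(k_folds, n)
  folds <- oplsda_folds(cls, groups, k_eff, seed)
  pred <- rep(NA_real_, n)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(cls[tr])) < 2) {
      stop("a CV fold left only one class in training; adjust k_folds")
    }
    core <- oplsda_core(X[tr, , drop = FALSE], y[tr], n_orth, scale_x)
    pred[!tr] <- oplsda_predict_core(core, X[!tr, , drop = FALSE])
  }
  q2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  acc <- mean((pred > 0.5) == (y > 0.5))
  list(q2 = q2, accuracy = acc, pred = pred)
}

oplsda_q2 <- function(X, y, cls, n_orth, k_folds, groups, seed, scale_x) {
  oplsda_cv(X, y, cls, n_orth, min(k_folds, nrow(X)), groups, seed, scale_x)$q2
}

#' @export
print.oplsda_model <- function(x, ...) {
  cat(sprintf("OPLS-DA (%s vs %s): %d orthogonal component(s)\n",
              x$classes[1], x$classes[2], ncol(x$W_orth)))
  cat(sprintf("  R2X = %.3f  R2Y = %.3f  Q2 = %.3f  CV accuracy = %.3f\n",
              x$r2x, x$r2y, x$q2, x$accuracy))
  invisible(x)
}

#' VIP scores of an OPLS-DA model
#'
#' Computed from the predictive component only (orthogonal components are by
#' construction unrelated to the class contrast): with a single predictive
#' component and unit-norm weights, `VIP_j = sqrt(p) * |w_j|`, preserving the
#' identity `mean(VIP^2) = 1`.
#'
#' @param model A [fit_oplsda()] model.
#' @return Named numeric vector of VIP scores.
#' @export
oplsda_vip <- function(model) {
  stopifnot(inherits(model, "oplsda_model"))
  w <- model$w_pred
  if (sum(model$t_pred^2) * model$q_pred^2 <= 0) {
    stop("degenerate model: predictive component explains no class variance")
  }
  scores <- sqrt(length(w)) * abs(w) / sqrt(sum(w^2))
  names(scores) <- names(model$x_mean)
  scores
}

#' Screen discriminating volatile markers between two groups
#'
#' Fits OPLS-DA on a deduplicated compound matrix and returns the compounds
#' whose VIP exceeds `threshold` (strictly), ordered by descending VIP, with
#' a secondary flag for VIP > 2 ("key differential compounds") and per-group
#' mean abundances.
#'
#' @param peak_matrix Observations x compounds matrix (normalized volumes;
#'   rows may be replicate injections).
#' @param groups Two-level class vector, one entry per row.
#' @param threshold VIP selection threshold (default 1).
#' @param ... Passed to [fit_oplsda()] (e.g. `groups` for replicate-safe CV
#'   as `cv_groups`, `seed`).
#' @param cv_groups Optional physical-sample labels for leakage-safe folds.
#' @param seed RNG seed.
#' @return `data.frame` with columns `compound`, `vip`, `vip_gt2`, and the
#'   two group means; attribute `"model"` holds the fitted OPLS-DA model.
#'   Empty result (with a warning) if nothing passes the threshold.
#' @export
screen_markers <- function(peak_matrix, groups, threshold = 1.0,
                           cv_groups = NULL, seed = 1L, ...) {
  X <- as.matrix(peak_matrix)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  model <- fit_oplsda(X, groups, groups = cv_groups, seed = seed, ...)
  v <- oplsda_vip(model)
  names(v) <- colnames(X)
  lev <- model$classes
  gmeans <- vapply(lev, function(l) {
    colMeans(X[groups == l, , drop = FALSE])
  }, numeric(ncol(X)))
  keep <- which(v > threshold)
  if (length(keep) == 0) {
    warning("no compound exceeded the VIP threshold; returning empty marker list")
  }
  ord <- keep[order(v[keep], decreasing = TRUE)]
  out <- data.frame(compound = colnames(X)[ord],
                    vip = unname(v[ord]),
                    vip_gt2 = unname(v[ord] > 2),
                    stringsAsFactors = FALSE)
  out[[paste0("mean_", lev[1])]] <- unname(gmeans[ord, 1])
  out[[paste0("mean_", lev[2])]] <- unname(gmeans[ord, 2])
  attr(out, "model") <- model
  attr(out, "vip_all") <- v
  out
}
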