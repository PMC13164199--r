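#' Stratified train/test split of a spectra set
#'
#' Assigns spectra to training and testing partitions at the given ratio,
#' stratified by storage class (sample label), deterministically per seed.
#' The default spectrum-level mode follows the acquisition protocol in which
#' all spectra are pooled before splitting; the sample-grouped mode keeps all
#' spectra of one physical sample together (an honest-generalization variant
#' that cannot stratify when there is only one sample per class).
#'
#' @param spectra A [spectra_set()].
#' @param ratio Training fraction (default 0.8).
#' @param seed RNG seed.
#' @param mode `"spectrum"` (default) or `"sample"`.
#' @return An object of class `split_plan` with integer vectors `train` and
#'   `test`.
#' @export
make_split <- function(spectra, ratio = 0.8, seed = 1L,
                       mode = c("spectrum", "sample")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spectra, "spectra_set"), ratio > 0, ratio < 1)
  cls <- as.character(spectra$meta$sample)
  n <- length(cls)
  if (mode == "sample") {
    # grouped mode assigns whole physical samples; stratification needs at
    # least two samples per storage class in order to fill both partitions
    groups_per_class <- tapply(spectra$meta$sample, cls,
                               function(g) length(unique(g)))
    if (any(groups_per_class < 2)) {
      stop("sample-grouped splitting cannot stratify: some storage class has ",
           "a single physical sample; use spectrum-level mode")
    }
  }
  train <- integer(0)
  with_local_seed(seed, {
    for (s in unique(cls)) {
      idx <- which(cls == s)
      n_tr <- round(length(idx) * ratio)
      if (n_tr < 1 || n_tr >= length(idx)) {
        stop(sprintf("class '%s' cannot appear in both partitions at ratio %.2f",
                     s, ratio))
      }
      train <- c(train, sample(idx, n_tr))
    }
  })
  train <- sort(train)
  structure(list(train = train, test = setdiff(seq_len(n), train),
                 ratio = ratio, seed = seed, mode = mode,
                 strata = cls),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split_plan: %d train / %d test (ratio %.2f, %s-level, seed %d)\n",
              length(x$train), length(x$test), x$ratio, x$mode, x$seed))
  invisible(x)
}

#' Classification screen over preprocessing methods and algorithms
#'
#' Preliminary assessment of how well the spectra discriminate storage
#' classes: for each preprocessing specification and each algorithm (SVM,
#' KNN, random forest -- standard implementations from e1071, class and
#' randomForest), preprocessing statistics are fitted on the training
#' partition only, models are evaluated by stratified k-fold cross-validation
#' within the training partition and once on the held-out test partition.
#' Metrics: accuracy, class-frequency-weighted F1 and weighted recall, plus
#' the test confusion matrix.
#'
#' @param spectra A [spectra_set()].
#' @param preprocess_specs Named list of [preprocess_spec()] objects.
#' @param algorithms Subset of `c("SVM", "KNN", "RF")`.
#' @param split A [make_split()] plan.
#' @param cv_k CV folds within the training partition (default 10,
#'   stratified).
#' @param seed RNG seed (folds, RF).
#' @param knn_k Neighbors for KNN (default 5).
#' @return `data.frame` of class `classifier_report` with one row per
#'   (preprocessing, algorithm); attribute `"confusion"` holds the test
#'   confusion matrices.
#' @export
classify_screen <- function(spectra, preprocess_specs,
                            algorithms = c("SVM", "KNN", "RF"),
                            split, cv_k = 10, seed = 1L, knn_k = 5) {
  stopifnot(inherits(spectra, "spectra_set"), inherits(split, "split_plan"))
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  cls <- factor(spectra$meta$sample)
  rows <- list()
  confusion <- list()

  fit_predict <- function(algo, X_tr, y_tr, X_te, fit_seed) {
    with_local_seed(fit_seed, switch(algo,
      SVM = {
        m <- e1071::svm(X_tr, y_tr, kernel = "radial")
        stats::predict(m, X_te)
      },
      KNN = class::knn(X_tr, X_te, y_tr, k = knn_k),
      RF = {
        m <- randomForest::randomForest(X_tr, y_tr)
        stats::predict(m, X_te)
      }
    ))
  }

  weighted_prf <- function(truth, pred) {
    lev <- levels(truth)
    support <- as.numeric(table(truth)[lev])
    prec <- rec <- f1 <- numeric(length(lev))
    for (i in seq_along(lev)) {
      tp <- sum(pred == lev[i] & truth == lev[i])
      fp <- sum(pred == lev[i] & truth != lev[i])
      fn <- sum(pred != lev[i] & truth == lev[i])
      prec[i] <- if (tp + fp == 0) 0 else tp / (tp + fp)
      rec[i] <- if (tp + fn == 0) 0 else tp / (tp + fn)
      f1[i] <- if (prec[i] + rec[i] == 0) 0 else
        2 * prec[i] * rec[i] / (prec[i] + rec[i])
    }
    w <- support / sum(support)
    c(accuracy = mean(pred == truth), f1 = sum(w * f1), recall = sum(w * rec))
  }

  for (spec_name in names(preprocess_specs)) {
    spec <- preprocess_specs[[spec_name]]
    tr_set <- subset_spectra(spectra, split$train)
    te_set <- subset_spectra(spectra, split$test)
    fit <- apply_pipeline(tr_set, spec)
    X_tr <- fit$spectra$absorbance
    X_te <- apply_pipeline(te_set, spec, fit$fitted_state)$spectra$absorbance
    y_tr <- droplevels(cls[split$train])
    y_te <- factor(cls[split$test], levels = levels(y_tr))

    folds <- make_folds(as.character(y_tr), min(cv_k, length(y_tr)), seed)
    for (algo in algorithms) {
      cv_pred <- factor(rep(NA_character_, length(y_tr)), levels = levels(y_tr))
      for (f in sort(unique(folds))) {
        hold <- folds == f
        cv_pred[hold] <- fit_predict(algo, X_tr[!hold, , drop = FALSE],
                                     y_tr[!hold], X_tr[hold, , drop = FALSE],
                                     seed + f)
      }
      te_pred <- fit_predict(algo, X_tr, y_tr, X_te, seed)
      m_cv <- weighted_prf(y_tr, cv_pred)
      m_te <- weighted_prf(y_te, te_pred)
      rows[[paste(spec_name, algo)]] <- data.frame(
        preprocessing = spec_name, algorithm = algo,
        acc_cv = m_cv["accuracy"], f1_cv = m_cv["f1"], recall_cv = m_cv["recall"],
        acc_test = m_te["accuracy"], f1_test = m_te["f1"],
        recall_test = m_te["recall"], row.names = NULL)
      confusion[[paste(spec_name, algo)]] <- table(truth = y_te, pred = te_pred)
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "confusion") <- confusion
  class(report) <- c("classifier_report", class(report))
  report
}

#' Calibrate a composite index against NIR spectra
#'
#' The central calibration step: for every preprocessing method, fit the
#' preprocessing on the training partition, select the latent-variable count
#' by stratified 5-fold cross-validation (maximizing pooled cross-validated
#' R2 over the 1-10 grid), refit on all training rows and evaluate on the
#' held-out test partition. Every spectrum carries the per-sample index value
#' of its physical sample. For the deterioration index, drop raw-sample
#' spectra before calling (or pass an index that omits the raw sample; rows
#' whose sample has no index value are dropped with a message).
#'
#' @param spectra A [spectra_set()].
#' @param index A [build_index()] result (or any named per-sample numeric
#'   vector).
#' @param preprocess_specs Named list of [preprocess_spec()]s (default all
#'   seven).
#' @param lv_grid Latent-variable grid (default `1:10`).
#' @param cv_k CV folds (default 5).
#' @param split A [make_split()] plan made on `spectra` *after* any row
#'   dropping, or `NULL` to create one internally.
#' @param seed RNG seed.
#' @return An object of class `calibration_report`: a `data.frame` with one
#'   row per method (columns `best_lv, Rcv2, RMSEcv, RPDcv, Rp2, RMSEp,
#'   RPDp, best` -- the best method maximizes `Rp2` with `RPDp` as
#'   tie-break); attribute `"models"` holds per-method fitted pipelines and
#'   PLS models.
#' @export
calibrate_index <- function(spectra, index,
                            preprocess_specs = all_preprocess_specs(),
                            lv_grid = 1:10, cv_k = 5, split = NULL,
                            seed = 1L) {
  stopifnot(inherits(spectra, "spectra_set"))
  values <- if (inherits(index, "composite_index")) index$values else index
  if (is.null(names(values))) stop("index must be named by sample label")

  covered <- spectra$meta$sample %in% names(values)
  if (!all(covered)) {
    message(sprintf("dropping %d spectra of samples without an index value (%s)",
                    sum(!covered),
                    paste(unique(spectra$meta$sample[!covered]), collapse = ", ")))
    spectra <- subset_spectra(spectra, which(covered))
  }
  y_all <- as.numeric(values[spectra$meta$sample])
  if (stats::sd(y_all) == 0) stop("degenerate response: index values all equal")

  if (is.null(split)) split <- make_split(spectra, seed = seed)
  tr_set <- subset_spectra(spectra, split$train)
  te_set <- subset_spectra(spectra, split$test)
  y_tr <- y_all[split$train]
  y_te <- y_all[split$test]
  strata_tr <- as.character(tr_set$meta$sample)

  rows <- list(); models <- list()
  for (spec_name in names(preprocess_specs)) {
    spec <- preprocess_specs[[spec_name]]
    fit <- apply_pipeline(tr_set, spec)
    X_tr <- fit$spectra$absorbance
    X_te <- apply_pipeline(te_set, spec, fit$fitted_state)$spectra$absorbance

    cv <- cross_validate_lv(X_tr, y_tr, lv_grid = lv_grid, k = cv_k,
                            strata = strata_tr, seed = seed)
    m_cv <- compute_metrics(y_tr, cv$cv_pred, context = "cv")
    m_te <- compute_metrics(y_te, predict(cv$model, X_te), context = "test")

    rows[[spec_name]] <- data.frame(
      preprocessing = spec_name, best_lv = cv$best_lv,
      Rcv2 = m_cv$r2, RMSEcv = m_cv$rmse, RPDcv = m_cv$rpd,
      Rp2 = m_te$r2, RMSEp = m_te$rmse, RPDp = m_te$rpd,
      row.names = NULL)
    models[[spec_name]] <- list(spec = spec, fitted_state = fit$fitted_state,
                                model = cv$model,
                                X_train = X_tr, y_train = y_tr)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  best_i <- order(-report$Rp2, -report$RPDp)[1]
  report$best <- seq_len(nrow(report)) == best_i
  attr(report, "models") <- models
  attr(report, "split") <- split
  class(report) <- c("calibration_report", class(report))
  report
}

#' High-contribution wavelength regions of a calibration model
#'
#' Reports contiguous wavelength regions whose absolute regression
#' coefficients exceed the given percentile of the |coefficient| profile,
#' ranked by their peak |coefficient|. On synthetic data these regions can be
#' checked against the generator's planted oxidation-band placements.
#'
#' @param model A [fit_pls1()] model fitted on spectra.
#' @param wavelengths Wavelength grid matching the model's predictors.
#' @param percentile Threshold percentile of |coefficients| (default 0.90).
#' @return `data.frame` with columns `start_nm`, `end_nm`, `peak_nm`,
#'   `peak_abs_coef`, ordered by descending peak magnitude; zero rows if the
#'   profile is flat.
#' @export
coefficient_profile <- function(model, wavelengths, percentile = 0.90) {
  stopifnot(inherits(model, "pls_model"))
  b <- abs(model$coefficients)
  if (length(b) != length(wavelengths)) {
    stop("wavelength grid does not match the coefficient vector")
  }
  thr <- if (percentile <= 0) -Inf else stats::quantile(b, percentile)
  above <- b > thr
  if (!any(above)) {
    return(data.frame(start_nm = numeric(), end_nm = numeric(),
                      peak_nm = numeric(), peak_abs_coef = numeric()))
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  out <- do.call(rbind, lapply(keep, function(i) {
    idx <- starts[i]:ends[i]
    peak <- idx[which.max(b[idx])]
    data.frame(start_nm = wavelengths[starts[i]], end_nm = wavelengths[ends[i]],
               peak_nm = wavelengths[peak], peak_abs_coef = b[peak])
  }))
  out[order(-out$peak_abs_coef), , drop = FALSE]
}

#' Permutation test of a PLSR calibration
#'
#' Guards against chance correlation: the response is randomly shuffled
#' `n_iter` times while the predictor matrix stays fixed; at each iteration
#' the model is refit at the *same* latent-variable count (no re-selection),
#' recording the training R2, the pooled k-fold cross-validated Q2, and the
#' absolute correlation between permuted and original responses. Straight
#' lines of R2 and Q2 against the correlation (including the unpermuted model
#' at correlation 1) are fit by least squares; a Q2 intercept below 0.05 at
#' correlation 0 indicates a model free from overfitting.
#'
#' @param X_train Training predictor matrix (already preprocessed).
#' @param y_train Training response.
#' @param n_lv Fixed latent-variable count of the calibrated model.
#' @param n_iter Number of permutations (default 200; < 20 warns).
#' @param cv_k CV folds for Q2 (default 5).
#' @param seed RNG seed.
#' @param strata Optional stratification labels for the CV folds.
#' @return An object of class `permutation_report` with the permuted
#'   `r2`/`q2`/`correlation` arrays, the original R2 and Q2, both
#'   intercepts, and `pass` (`q2_intercept < 0.05`).
#' @export
permutation_test <- function(X_train, y_train, n_lv, n_iter = 200, cv_k = 5,
                             seed = 1L, strata = NULL) {
  X <- as.matrix(X_train); y <- as.numeric(y_train)
  n <- nrow(X)
  if (n_iter < 20) warning("fewer than 20 permutations: intercept estimate is unstable")

  q2_of <- function(yy, fold_seed) {
    folds <- make_folds(strata %||% rep("all", n), min(cv_k, n), fold_seed)
    pred <- rep(NA_real_, n)
    for (f in sort(unique(folds))) {
      tr <- folds != f
      m <- fit_pls1(X[tr, , drop = FALSE], yy[tr],
                    n_lv = min(n_lv, sum(tr) - 1L, ncol(X)))
      pred[!tr] <- predict(m, X[!tr, , drop = FALSE])
    }
    1 - sum((yy - pred)^2) / sum((yy - mean(yy))^2)
  }
  r2_of <- function(yy) {
    m <- fit_pls1(X, yy, n_lv = min(n_lv, n - 1L, ncol(X)))
    1 - sum((yy - predict(m, X))^2) / sum((yy - mean(yy))^2)
  }

  orig_r2 <- r2_of(y)
  orig_q2 <- q2_of(y, seed)

  perm_r2 <- perm_q2 <- perm_cor <- numeric(n_iter)
  with_local_seed(seed + 1L, {
    for (i in seq_len(n_iter)) {
      yp <- sample(y)
      perm_cor[i] <- abs(stats::cor(yp, y))
      perm_r2[i] <- r2_of(yp)
      perm_q2[i] <- q2_of(yp, seed + i)
    }
  })

  xs <- c(perm_cor, 1)
  fit_r2 <- stats::lm.fit(cbind(1, xs), c(perm_r2, orig_r2))
  fit_q2 <- stats::lm.fit(cbind(1, xs), c(perm_q2, orig_q2))
  r2_int <- unname(fit_r2$coefficients[1])
  q2_int <- unname(fit_q2$coefficients[1])

  structure(
    list(n_iter = n_iter, n_lv = n_lv,
         perm_r2 = perm_r2, perm_q2 = perm_q2, perm_cor = perm_cor,
         original_r2 = orig_r2, original_q2 = orig_q2,
         r2_intercept = r2_int, q2_intercept = q2_int,
         pass = q2_int < 0.05, seed = seed),
    class = "permutation_report"
  )
}

#' @export
print.permutation_report <- function(x, ...) {
  cat(sprintf("permutation test (%d iterations, %d LVs)\n", x$n_iter, x$n_lv))
  cat(sprintf("  original R2 = %.3f, Q2 = %.3f\n", x$original_r2, x$original_q2))
  cat(sprintf("  intercepts at correlation 0: R2 %.3f, Q2 %.3f -> %s\n",
              x$r2_intercept, x$q2_intercept,
              if (x$pass) "PASS (Q2 intercept < 0.05)" else "FAIL"))
  invisible(x)
}
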