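#' Cross-validated grid tuning with repeated half-partitions
#'
#' Draws `n_partitions` random partitions of the training samples, each
#' assigning every sample to the retained group with probability
#' `1 - holdout_fraction` (default: half splits). The same partitions are
#' used consistently across the whole parameter grid: for every grid
#' point and every partition the model is fitted on the retained group
#' and the RMSE is computed on the held-out group. A partition whose
#' held-out (or retained) response is degenerate is redrawn and the event
#' logged in the result.
#'
#' @param X training predictor matrix.
#' @param y training response.
#' @param family a model family (see [pls_family()]).
#' @param grid non-empty list of parameter lists.
#' @param n_partitions number of random partitions.
#' @param holdout_fraction selection probability for the held-out group.
#' @param seed integer seed; the result is deterministic under it.
#' @return An object of class `tuning_result`: `grid`, `rmse`
#'   (grid x partitions), `mean`, `se` (SD over partitions / sqrt of
#'   `n_partitions`), `partitions` (logical matrix, TRUE = held out),
#'   `complexity`, `redraws`, `seed`, `family`.
#' @export
cv_tune <- function(X, y, family, grid, n_partitions = 10,
                    holdout_fraction = 0.5, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (!length(grid)) stop("grid must be non-empty", call. = FALSE)
  redraws <- 0L
  parts <- withr::with_seed(as.integer(seed), {
    P <- matrix(FALSE, n, n_partitions)
    for (j in seq_len(n_partitions)) {
      repeat {
        hold <- stats::runif(n) < holdout_fraction
        ok <- sum(hold) >= 2 && sum(!hold) >= 2 &&
          stats::sd(y[hold]) > 0 && stats::sd(y[!hold]) > 0
        if (ok) break
        redraws <- redraws + 1L
      }
      P[, j] <- hold
    }
    P
  })
  rmse <- matrix(NA_real_, length(grid), n_partitions)
  for (j in seq_len(n_partitions)) {
    hold <- parts[, j]
    path <- if (!is.null(family$cv_path))
      family$cv_path(X[!hold, , drop = FALSE], y[!hold],
                     X[hold, , drop = FALSE], y[hold], grid)
    else NULL
    if (!is.null(path)) {
      rmse[, j] <- path
    } else {
      for (g in seq_along(grid)) {
        fit <- family$fit(X[!hold, , drop = FALSE], y[!hold], grid[[g]])
        pred <- family$predict(fit, X[hold, , drop = FALSE])
        rmse[g, j] <- sqrt(mean((pred - y[hold])^2))
      }
    }
  }
  structure(list(grid = grid, rmse = rmse,
                 mean = rowMeans(rmse),
                 se = apply(rmse, 1, stats::sd) / sqrt(n_partitions),
                 partitions = parts,
                 complexity = vapply(grid, family$complexity, numeric(1)),
                 redraws = redraws, seed = as.integer(seed),
                 family = family$name),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result> %s family, %d grid points x %d partitions\n",
              x$family, length(x$grid), ncol(x$rmse)))
  invisible(x)
}

#' One-standard-error model selection
#'
#' Let `(m*, se*)` be the mean CV RMSE and its standard error at the grid
#' point with the minimal mean. The selected point is the least complex
#' one whose mean RMSE is at most `m* + se*`; with all-zero standard
#' errors this is the argmin itself, and with all means equal it is the
#' least complex point.
#'
#' @param tuning a [cv_tune()] result.
#' @param complexity optional numeric complexity per grid point
#'   (defaults to the family's ordering stored in `tuning`).
#' @return list `index`, `params`, `mean`, `se`, `threshold`.
#' @export
one_se_select <- function(tuning, complexity = tuning$complexity) {
  stopifnot(inherits(tuning, "tuning_result"))
  best <- which.min(tuning$mean)
  thr <- tuning$mean[best] + tuning$se[best]
  ok <- which(tuning$mean <= thr + 1e-12)
  idx <- ok[order(complexity[ok], ok)][1]
  list(index = idx, params = tuning$grid[[idx]],
       mean = tuning$mean[idx], se = tuning$se[idx], threshold = thr)
}

#' Recursive feature elimination
#'
#' Backward predictor selection: a full model (fitted with the least
#' complex adequate parameters chosen by [cv_tune()] and
#' [one_se_select()] on all predictors) ranks the predictors by the
#' family's importance measure; for each candidate size the top-ranked
#' predictors are re-evaluated with the same cross-validation machinery;
#' the size whose selected model achieves the lowest mean CV RMSE is
#' retained (ties toward fewer predictors).
#'
#' @param X training predictor matrix.
#' @param y training response.
#' @param family a model family exposing an importance measure.
#' @param sizes decreasing sequence of candidate predictor counts, all
#'   `<= ncol(X)`.
#' @param grid parameter grid passed to [cv_tune()].
#' @param n_partitions,holdout_fraction,seed see [cv_tune()].
#' @return An object of class `rfe_result`: `sizes`, `cv_mean`, `cv_se`,
#'   `chosen_size`, `selected` (column indices into `X`), `ranking`
#'   (full-model importance order, best first), `per_size` (chosen
#'   params and tuning per size).
#' @export
rfe <- function(X, y, family, sizes, grid, n_partitions = 10,
                holdout_fraction = 0.5, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(family$importance))
    stop(sprintf("family '%s' has no importance measure; RFE unavailable",
                 family$name), call. = FALSE)
  sizes <- as.integer(sizes)
  if (is.unsorted(rev(sizes)))
    stop("sizes must be sorted in decreasing order", call. = FALSE)
  if (any(sizes > ncol(X)) || any(sizes < 1))
    stop("sizes must lie in [1, ncol(X)]", call. = FALSE)
  full_tune <- cv_tune(X, y, family, grid, n_partitions, holdout_fraction,
                       seed)
  full_sel <- one_se_select(full_tune)
  full_fit <- family$fit(X, y, full_sel$params)
  imp <- family$importance(full_fit)
  if (is.null(imp) || length(imp) != ncol(X))
    stop(sprintf("family '%s' returned no usable importance", family$name),
         call. = FALSE)
  ranking <- order(imp, decreasing = TRUE)
  cv_mean <- cv_se <- numeric(length(sizes))
  per_size <- vector("list", length(sizes))
  for (s in seq_along(sizes)) {
    idx <- sort(ranking[seq_len(sizes[s])])
    tune_s <- if (sizes[s] == ncol(X)) full_tune else
      cv_tune(X[, idx, drop = FALSE], y, family, grid, n_partitions,
              holdout_fraction, seed)
    sel_s <- one_se_select(tune_s)
    cv_mean[s] <- sel_s$mean
    cv_se[s] <- sel_s$se
    per_size[[s]] <- list(size = sizes[s], indices = idx, params = sel_s$params)
  }
  best <- order(cv_mean, sizes)[1]    # ties -> fewer predictors
  structure(list(sizes = sizes, cv_mean = cv_mean, cv_se = cv_se,
                 chosen_size = sizes[best],
                 selected = per_size[[best]]$indices,
                 chosen_params = per_size[[best]]$params,
                 ranking = ranking, importance = imp,
                 per_size = per_size),
            class = "rfe_result")
}

#' Predictor recipe
#'
#' Describes how the model's predictor matrix is assembled from the
#' pre-treated spectra: either the full spectral matrix or the
#' RFE-selected bands, optionally fused with auxiliary particle-size
#' predictors. When the source is the full spectral matrix the fusion
#' compresses the spectra to PCA scores (>99% variance) before attaching
#' the auxiliary columns and scaling; when the source is RFE-selected the
#' matrix is assumed already reduced to its intrinsic dimensionality and
#' is only scaled.
#'
#' @param source `"spectra"` or `"rfe"`.
#' @param auxiliary `"none"`, `"sand"`, `"clay"` or `"both"`.
#' @return list `source`, `auxiliary`, `fusion` (`"pca_scores_99"`,
#'   `"scale_only"` or `"none"`).
#' @export
predictor_recipe <- function(source = c("spectra", "rfe"),
                             auxiliary = c("none", "sand", "clay", "both")) {
  source <- match.arg(source)
  auxiliary <- match.arg(auxiliary)
  fusion <- if (auxiliary == "none") "none"
            else if (source == "rfe") "scale_only" else "pca_scores_99"
  list(source = source, auxiliary = auxiliary, fusion = fusion)
}

#' Fuse spectra-derived predictors with auxiliary columns
#'
#' `pca_scores_99` mode: PCA scores of the training matrix explaining
#' more than `var_threshold` of its variance are attached to the
#' auxiliary columns and every resulting column is centred and scaled to
#' unit variance. `scale_only` mode: the predictor matrix itself is
#' attached to the auxiliary columns and scaled, without the PCA step.
#' All constants (PCA centre/loadings, column means/SDs) are estimated on
#' the training rows only and frozen for test-time projection.
#'
#' @param X training predictor matrix (spectra-derived).
#' @param aux data.frame or matrix of auxiliary columns aligned with `X`
#'   rows; no missing values (texture is not analyzed for organic
#'   samples, so auxiliary predictors are available for mineral subsets
#'   only).
#' @param mode `"pca_scores_99"` or `"scale_only"`.
#' @param var_threshold PCA explained-variance threshold.
#' @return An object of class `fusion`: `train` (fused training matrix),
#'   `mode`, and frozen constants; project new data with
#'   [fusion_project()].
#' @export
fuse_auxiliary <- function(X, aux, mode = c("pca_scores_99", "scale_only"),
                           var_threshold = 0.99) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  aux <- as.matrix(aux)
  if (nrow(aux) != nrow(X))
    stop("aux and X are not aligned", call. = FALSE)
  if (anyNA(aux))
    stop(paste("auxiliary predictors contain missing values;",
               "texture analyses are not available for organic samples"),
         call. = FALSE)
  pca <- NULL
  base <- if (mode == "pca_scores_99") {
    pca <- pca_fit(X, var_threshold)
    pca$scores
  } else X
  fused <- cbind(base, aux)
  mu <- colMeans(fused)
  sdv <- apply(fused, 2, stats::sd)
  if (any(sdv == 0)) {
    bad <- which(sdv == 0)[1]
    stop(sprintf("fused column %d ('%s') has zero variance and cannot be scaled",
                 bad, colnames(fused)[bad] %||% as.character(bad)),
         call. = FALSE)
  }
  structure(list(train = sweep(sweep(fused, 2, mu), 2, sdv, "/"),
                 mode = mode, pca = pca, center = mu, scale = sdv,
                 n_aux = ncol(aux)),
            class = "fusion")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Project new data through a fitted fusion
#'
#' @param fusion a [fuse_auxiliary()] result.
#' @param X new spectra-derived predictor matrix.
#' @param aux new auxiliary columns.
#' @return fused, scaled predictor matrix.
#' @export
fusion_project <- function(fusion, X, aux) {
  stopifnot(inherits(fusion, "fusion"))
  X <- as.matrix(X); aux <- as.matrix(aux)
  if (anyNA(aux)) stop("auxiliary predictors contain missing values",
                       call. = FALSE)
  base <- if (fusion$mode == "pca_scores_99") pca_project(fusion$pca, X) else X
  fused <- cbind(base, aux)
  sweep(sweep(fused, 2, fusion$center), 2, fusion$scale, "/")
}

aux_columns <- function(props, auxiliary) {
  switch(auxiliary,
         none = NULL,
         sand = props[, "sand", drop = FALSE],
         clay = props[, "clay", drop = FALSE],
         both = props[, c("sand", "clay")])
}

#' Train a calibration model end to end
#'
#' Composes the full workflow on one library subset: design-matrix
#' construction ([build_design_matrix()]), Kennard-Stone train/test
#' partitioning ([split_library()]), optional recursive feature
#' elimination and auxiliary fusion on the training rows, grid tuning by
#' repeated half-split cross-validation with one-standard-error
#' selection, a final fit on all training samples, and validation
#' statistics on the untouched test set. All data-dependent constants
#' (RFE ranking, fusion centring/scaling/PCA) are computed on training
#' rows only.
#'
#' @param lib a `spectral_library`.
#' @param subset `"all"` or one of `"mineral"`, `"organic"`,
#'   `"cropland"`, `"grassland"`, `"woodland"` (the last three select
#'   mineral samples under that land cover).
#' @param pretreatment design-matrix recipe (see [build_design_matrix()]).
#' @param predictor a [predictor_recipe()].
#' @param family a model family (see [pls_family()]).
#' @param grid parameter grid (default [pls_grid()]).
#' @param seed integer seed driving the CV partitions.
#' @param rfe_sizes candidate sizes when `predictor$source == "rfe"`
#'   (default: all, 100, 50, 25, 10, capped at the predictor count).
#' @param ks_fraction Kennard-Stone training fraction.
#' @param qc_threshold scan QC threshold.
#' @param n_partitions CV partitions.
#' @return An object of class `calibration_model` with the fitted model,
#'   recipes, tuning/RFE audit trail, the selection result, test-set
#'   predictions and [prediction_stats()].
#' @export
train_model <- function(lib, subset = "mineral", pretreatment = "SG1",
                        predictor = predictor_recipe(),
                        family = pls_family(), grid = pls_grid(),
                        seed = 1L, rfe_sizes = NULL, ks_fraction = 2 / 3,
                        qc_threshold = 0.01, n_partitions = 10) {
  stopifnot(inherits(lib, "spectral_library"))
  if (subset == "organic" && predictor$auxiliary != "none")
    stop(paste("auxiliary particle-size predictors are unavailable for the",
               "organic subset (texture is not analyzed on organic samples)"),
         call. = FALSE)
  props <- lib$properties
  keep <- switch(subset,
                 all = rep(TRUE, nrow(props)),
                 mineral = props$material == "mineral",
                 organic = props$material == "organic",
                 cropland = ,
                 grassland = ,
                 woodland = props$material == "mineral" &
                   props$land_cover == subset,
                 stop(sprintf("unknown subset '%s'", subset), call. = FALSE))
  lib <- subset_library(lib, which(keep))
  design <- build_design_matrix(lib, pretreatment,
                                qc_threshold = qc_threshold)
  qc <- attr(design, "qc")
  lib <- subset_library(lib, rownames(design$values))
  split <- split_library(lib, fraction = ks_fraction)
  tr <- split$train; te <- split$test
  props <- lib$properties
  y <- props$soc
  X <- design$values
  rfe_res <- NULL
  cols <- seq_len(ncol(X))
  if (predictor$source == "rfe") {
    if (is.null(rfe_sizes))
      rfe_sizes <- unique(pmin(c(ncol(X), 100, 50, 25, 10), ncol(X)))
    rfe_res <- rfe(X[tr, , drop = FALSE], y[tr], family,
                   sizes = sort(rfe_sizes, decreasing = TRUE), grid = grid,
                   n_partitions = n_partitions, seed = as.integer(seed) + 1L)
    cols <- rfe_res$selected
  }
  Xtr <- X[tr, cols, drop = FALSE]
  Xte <- X[te, cols, drop = FALSE]
  fusion <- NULL
  if (predictor$auxiliary != "none") {
    aux <- aux_columns(props, predictor$auxiliary)
    fusion <- fuse_auxiliary(Xtr, aux[tr, , drop = FALSE],
                             mode = predictor$fusion)
    Xtr_f <- fusion$train
    Xte_f <- fusion_project(fusion, Xte, aux[te, , drop = FALSE])
  } else {
    Xtr_f <- Xtr
    Xte_f <- Xte
  }
  grid_ok <- Filter(function(p) is.null(p$n_lv) ||
                      p$n_lv <= min(nrow(Xtr_f) - 1, ncol(Xtr_f)), grid)
  if (!length(grid_ok))
    stop("no feasible grid point for the fused predictor matrix",
         call. = FALSE)
  tuning <- cv_tune(Xtr_f, y[tr], family, grid_ok,
                    n_partitions = n_partitions, seed = as.integer(seed))
  chosen <- one_se_select(tuning)
  fit <- family$fit(Xtr_f, y[tr], chosen$params)
  pred <- family$predict(fit, Xte_f)
  stats <- prediction_stats(y[te], pred)
  structure(list(fit = fit, family = family, subset = subset,
                 pretreatment = pretreatment, predictor = predictor,
                 columns = cols, fusion = fusion, rfe = rfe_res,
                 tuning = tuning, chosen = chosen, split = split, qc = qc,
                 seed = as.integer(seed),
                 test = data.frame(sample_id = props$sample_id[te],
                                   observed = y[te], predicted = pred,
                                   stringsAsFactors = FALSE),
                 stats = stats),
            class = "calibration_model")
}

#' Predict SOC for new pre-treated spectra
#'
#' @param object a [train_model()] result.
#' @param newdata pre-treated predictor matrix on the model's full band
#'   set (before RFE column selection).
#' @param aux auxiliary columns when the model uses them.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.calibration_model <- function(object, newdata, aux = NULL, ...) {
  X <- as.matrix(newdata)[, object$columns, drop = FALSE]
  Xf <- if (!is.null(object$fusion)) {
    if (is.null(aux)) stop("model requires auxiliary columns", call. = FALSE)
    fusion_project(object$fusion, X, aux)
  } else X
  object$family$predict(object$fit, Xf)
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %s | %s | %s | aux=%s\n", x$subset,
              x$pretreatment, x$family$name, x$predictor$auxiliary))
  s <- x$stats
  cat(sprintf("  test n=%d RMSEP=%.3g bias=%.3g RPD=%.3g R2=%.3g\n",
              s$n, s$rmsep, s$bias, s$rpd, s$r2))
  invisible(x)
}
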