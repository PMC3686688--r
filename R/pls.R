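#' Partial least squares regression (univariate response)
#'
#' First-principles NIPALS implementation for a single response. Each
#' latent variable maximizes the covariance between the predictor score
#' and the (deflated) response; predictors and response are deflated
#' after every component. Regression coefficients are returned on the
#' original predictor scale. With as many components as the rank of a
#' full-rank tall problem, PLS predictions coincide with ordinary least
#' squares.
#'
#' @param X predictor matrix (n x p), finite.
#' @param y response vector (length n), finite, non-constant (unless all
#'   coefficients are to be zero).
#' @param n_lv number of latent variables,
#'   `<= min(n - 1, p)`.
#' @param scale scale predictor columns to unit variance before fitting?
#' @return An object of class `pls_model`: `coefficients` (length p, on
#'   the original scale), `intercept`, `n_lv`, `weights`, `scores`,
#'   `loadings`, `y_loadings`, `x_center`, `x_scale`, `y_center`,
#'   `fitted`.
#' @export
pls_fit <- function(X, y, n_lv, scale = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("X and y must be finite", call. = FALSE)
  if (n_lv < 1 || n_lv > min(n - 1, p))
    stop(sprintf("n_lv must be in [1, min(n-1, p)] = [1, %d]", min(n - 1, p)),
         call. = FALSE)
  x_center <- colMeans(X)
  x_scale <- if (scale) apply(X, 2, stats::sd) else rep(1, p)
  if (any(x_scale == 0))
    stop("zero-variance predictor cannot be scaled", call. = FALSE)
  y_center <- mean(y)
  Xd <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  yd <- y - y_center
  y_const <- sum(yd^2) < 1e-28
  W <- P <- matrix(0, p, n_lv)
  TT <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  a_used <- 0
  if (!y_const) {
    for (a in seq_len(n_lv)) {
      w <- drop(crossprod(Xd, yd))
      wn <- sqrt(sum(w^2))
      if (wn < 1e-14) break           # residual X orthogonal to y: rank exhausted
      w <- w / wn
      tt <- drop(Xd %*% w)
      t2 <- sum(tt^2)
      if (t2 < 1e-24) break
      pp <- drop(crossprod(Xd, tt)) / t2
      qa <- sum(yd * tt) / t2
      Xd <- Xd - tcrossprod(tt, pp)
      yd <- yd - qa * tt
      W[, a] <- w; P[, a] <- pp; TT[, a] <- tt; q[a] <- qa
      a_used <- a
    }
  }
  if (a_used == 0) {
    beta <- rep(0, p)
  } else {
    W <- W[, 1:a_used, drop = FALSE]
    P <- P[, 1:a_used, drop = FALSE]
    TT <- TT[, 1:a_used, drop = FALSE]
    q <- q[1:a_used]
    beta <- drop(W %*% solve(crossprod(P, W), q)) / x_scale
  }
  intercept <- y_center - sum(x_center * beta)
  structure(list(coefficients = beta, intercept = intercept,
                 n_lv = a_used, n_lv_requested = n_lv,
                 weights = if (a_used) W else NULL,
                 scores = if (a_used) TT else NULL,
                 loadings = if (a_used) P else NULL,
                 y_loadings = if (a_used) q else NULL,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center,
                 fitted = intercept + drop(X %*% beta)),
            class = "pls_model")
}

#' Predict from a fitted PLS model
#'
#' Pure function: `intercept + X %*% coefficients`.
#'
#' @param object a [pls_fit()] model.
#' @param newdata predictor matrix with the training column count.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$coefficients))
    stop("newdata column count does not match the training predictors",
         call. = FALSE)
  object$intercept + drop(X %*% object$coefficients)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variable(s), %d predictors\n",
              x$n_lv, length(x$coefficients)))
  invisible(x)
}

# Held-out RMSE along the whole latent-variable path from a single
# decomposition. NIPALS components are nested (deflation is sequential),
# so the k-component coefficients from one max-rank fit equal a separate
# k-component fit. Components requested beyond the achievable rank reuse
# the last available ones (the model has converged there).
pls_path_rmse <- function(Xtr, ytr, Xte, yte, ks, scale = FALSE) {
  Xtr <- as.matrix(Xtr)
  max_k <- min(max(ks), nrow(Xtr) - 1, ncol(Xtr))
  x_center <- colMeans(Xtr)
  x_scale <- if (scale) apply(Xtr, 2, stats::sd) else rep(1, ncol(Xtr))
  y_center <- mean(ytr)
  Xd <- sweep(sweep(Xtr, 2, x_center), 2, x_scale, "/")
  yd <- ytr - y_center
  Xted <- sweep(sweep(as.matrix(Xte), 2, x_center), 2, x_scale, "/")
  W <- P <- matrix(0, ncol(Xtr), max_k)
  q <- numeric(max_k)
  rmse_k <- rep(NA_real_, max_k)
  a_used <- 0
  pred0 <- rep(y_center, nrow(Xted))
  for (a in seq_len(max_k)) {
    w <- drop(crossprod(Xd, yd))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-14) break
    w <- w / wn
    tt <- drop(Xd %*% w)
    t2 <- sum(tt^2)
    if (t2 < 1e-24) break
    pp <- drop(crossprod(Xd, tt)) / t2
    qa <- sum(yd * tt) / t2
    Xd <- Xd - tcrossprod(tt, pp)
    yd <- yd - qa * tt
    W[, a] <- w; P[, a] <- pp; q[a] <- qa
    beta <- drop(W[, 1:a, drop = FALSE] %*%
                   solve(crossprod(P[, 1:a, drop = FALSE],
                                   W[, 1:a, drop = FALSE]), q[1:a]))
    pred <- pred0 + drop(Xted %*% beta)
    rmse_k[a] <- sqrt(mean((pred - yte)^2))
    a_used <- a
  }
  if (a_used == 0) rmse_k[] <- sqrt(mean((pred0 - yte)^2))
  else if (a_used < max_k) rmse_k[(a_used + 1):max_k] <- rmse_k[a_used]
  rmse_k[pmin(ks, max_k)]
}

#' Model-family contract
#'
#' A model family is a list with elements `name`, `fit(X, y, params)`,
#' `predict(fit, X)`, `importance(fit)` (a non-negative score per
#' predictor, or NULL when the family has none) and `complexity(params)`
#' (a numeric used as the ordering for the one-standard-error rule: lower
#' is simpler). `pls_family()` is the implemented core; other families
#' (kernel, tree-ensemble, rule-based) plug in through the same contract.
#'
#' For PLS, `params` is `list(n_lv = k)`; importance is the absolute
#' regression coefficient on standardized predictors, `|b_j| * sd(x_j)`.
#'
#' @param scale scale predictors inside each fit?
#' @return a model-family list.
#' @export
pls_family <- function(scale = FALSE) {
  list(
    name = "pls",
    fit = function(X, y, params) {
      f <- pls_fit(X, y, n_lv = params$n_lv, scale = scale)
      f$train_sd <- apply(as.matrix(X), 2, stats::sd)
      f
    },
    predict = function(fit, X) predict.pls_model(fit, X),
    importance = function(fit) abs(fit$coefficients) * fit$train_sd,
    complexity = function(params) params$n_lv,
    # fast CV: one decomposition per partition covers the whole grid
    cv_path = function(Xtr, ytr, Xte, yte, grid) {
      ks <- vapply(grid, function(p) p$n_lv %||% NA_integer_, numeric(1))
      if (anyNA(ks)) return(NULL)
      pls_path_rmse(Xtr, ytr, Xte, yte, as.integer(ks), scale = scale)
    }
  )
}

#' Parameter grid for the PLS family
#'
#' @param max_lv largest number of latent variables (default 20).
#' @param min_lv smallest (default 1).
#' @return list of `list(n_lv = k)` grid points.
#' @export
pls_grid <- function(max_lv = 20, min_lv = 1) {
  lapply(seq(min_lv, max_lv), function(k) list(n_lv = k))
}

#' Random-forest model family (ranger backend)
#'
#' Demonstrates the pluggable family contract with an external learner;
#' its permutation/impurity importance makes it usable for recursive
#' feature elimination. Requires the `ranger` package.
#'
#' @param num_trees trees per forest.
#' @return a model-family list (see [pls_family()]).
#' @export
rf_family <- function(num_trees = 200) {
  if (!requireNamespace("ranger", quietly = TRUE))
    stop("rf_family requires the 'ranger' package", call. = FALSE)
  list(
    name = "rf",
    fit = function(X, y, params) {
      mtry <- max(1, min(ncol(X), floor(params$mtry)))
      d <- as.data.frame(X)
      names(d) <- paste0("V", seq_len(ncol(X)))
      d$.y <- y
      ranger::ranger(dependent.variable.name = ".y", data = d,
                     num.trees = num_trees, mtry = mtry,
                     importance = "impurity", seed = 1)
    },
    predict = function(fit, X) {
      d <- as.data.frame(X)
      names(d) <- paste0("V", seq_len(ncol(X)))
      stats::predict(fit, data = d)$predictions
    },
    importance = function(fit) as.numeric(fit$variable.importance),
    complexity = function(params) params$mtry
  )
}
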