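#' Principal component analysis of a spectra matrix
#'
#' Eigendecomposition (via SVD) of the column-centred spectra matrix.
#' The retained components are the minimal leading set whose cumulative
#' explained variance exceeds `var_threshold`; their scores are
#' additionally normalized to unit variance, giving the "normalized score
#' space" in which sample-selection distances are Euclidean
#' (Mahalanobis-like in the retained subspace).
#'
#' @param m a [spectra_matrix()] or plain numeric matrix.
#' @param var_threshold cumulative explained-variance threshold in (0, 1).
#' @return An object of class `pca_model`: `loadings` (bands x k),
#'   `eigenvalues` (all), `explained` (fractions, all), `n_retained`,
#'   `scores` (raw, n x k), `scores_norm` (unit-variance), `center`,
#'   `score_sd` (normalization constants), `wavelengths`.
#' @export
pca_fit <- function(m, var_threshold = 0.99) {
  X <- if (inherits(m, "spectra_matrix")) m$values else as.matrix(m)
  wl <- if (inherits(m, "spectra_matrix")) m$wavelengths else NULL
  stopifnot(var_threshold > 0, var_threshold < 1)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  if (all(abs(Xc) < 1e-14))
    stop("zero-variance matrix: PCA undefined", call. = FALSE)
  sv <- svd(Xc)
  n <- nrow(X)
  eig <- sv$d^2 / (n - 1)
  expl <- eig / sum(eig)
  k <- which(cumsum(expl) > var_threshold)[1]
  if (is.na(k)) k <- length(expl)
  if (k >= n)
    stop("number of retained components must be below n_samples",
         call. = FALSE)
  scores <- sv$u[, 1:k, drop = FALSE] %*% diag(sv$d[1:k], k)
  score_sd <- sqrt(eig[1:k])
  structure(list(loadings = sv$v[, 1:k, drop = FALSE],
                 eigenvalues = eig, explained = expl, n_retained = k,
                 scores = scores,
                 scores_norm = sweep(scores, 2, score_sd, "/"),
                 center = ctr, score_sd = score_sd, wavelengths = wl),
            class = "pca_model")
}

#' Project new spectra onto a fitted PCA model
#'
#' @param model a [pca_fit()] result.
#' @param m a [spectra_matrix()] or matrix with the same bands.
#' @param normalized return unit-variance-normalized scores?
#' @return Score matrix (n x k).
#' @export
pca_project <- function(model, m, normalized = FALSE) {
  X <- if (inherits(m, "spectra_matrix")) m$values else as.matrix(m)
  if (ncol(X) != length(model$center))
    stop("band mismatch between model and new spectra", call. = FALSE)
  s <- sweep(X, 2, model$center) %*% model$loadings
  if (normalized) s <- sweep(s, 2, model$score_sd, "/")
  s
}

#' Correlation of component scores with soil properties
#'
#' Pearson correlation of each retained component's scores with each
#' numeric soil property, mirroring the exploratory score-property tables
#' used to interpret spectral libraries. Constant properties yield `NA`
#' (the correlation is undefined, not zero).
#'
#' @param model a [pca_fit()] result.
#' @param props property data.frame aligned with the scored samples.
#' @param k number of leading components to report.
#' @return data.frame `property`, `component`, `rho`.
#' @export
property_correlations <- function(model, props, k = 3) {
  stopifnot(inherits(model, "pca_model"))
  k <- min(k, model$n_retained)
  num <- names(props)[vapply(props, is.numeric, logical(1))]
  if (nrow(props) != nrow(model$scores))
    stop("properties and scores are not aligned", call. = FALSE)
  out <- expand.grid(property = num, component = seq_len(k),
                     stringsAsFactors = FALSE)
  out$rho <- mapply(function(p, j) {
    x <- props[[p]]
    ok <- !is.na(x)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], model$scores[ok, j])
  }, out$property, out$component)
  out
}

#' Kennard-Stone maximin sample selection
#'
#' Deterministic space-filling selection in predictor space. The first
#' two selected points are the pair with the largest Euclidean distance;
#' thereafter the candidate whose distance to its nearest already-selected
#' neighbour is largest is added, until `n_train` points are selected.
#' Ties are broken toward the lowest sample index. The maximin distance
#' recorded for each accepted point is non-increasing after the initial
#' pair.
#'
#' @param scores numeric matrix of predictor coordinates (typically
#'   normalized PCA scores), samples in rows.
#' @param n_train number of samples to select (2 <= n_train <= n).
#' @return An object of class `selection_result`: `train` (sorted
#'   indices), `test` (sorted indices), `order` (selection order),
#'   `distance` (maximin distance trace, one value per accepted point;
#'   the initial pair shares the pair distance), `tie_break`.
#' @export
kennard_stone <- function(scores, n_train) {
  X <- as.matrix(scores)
  n <- nrow(X)
  stopifnot(n_train >= 2, n_train <= n)
  D <- as.matrix(stats::dist(X))
  dimnames(D) <- NULL
  # initial pair: largest pairwise distance, lowest indices on ties
  dmax <- max(D)
  pair <- which(D == dmax, arr.ind = TRUE)
  pair <- pair[pair[, 1] < pair[, 2], , drop = FALSE]
  pair <- pair[order(pair[, 1], pair[, 2]), , drop = FALSE][1, ]
  sel <- as.integer(pair)
  trace <- c(dmax, dmax)
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  mind[sel] <- -Inf
  while (length(sel) < n_train) {
    nxt <- which.max(mind)            # ties -> lowest index
    sel <- c(sel, nxt)
    trace <- c(trace, mind[nxt])
    mind <- pmin(mind, D[, nxt])
    mind[nxt] <- -Inf
  }
  structure(list(train = sort(sel), test = sort(setdiff(seq_len(n), sel)),
                 order = sel, distance = trace,
                 tie_break = "lowest index"),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d train / %d test (maximin d: %.4g .. %.4g)\n",
              length(x$train), length(x$test),
              x$distance[1], x$distance[length(x$distance)]))
  invisible(x)
}

# nearest-integer rounding, halves away from zero (not banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Split a library into calibration and test sets
#'
#' Implements the standard library-splitting procedure: scans are
#' averaged, converted to absorbance, splice-corrected and converted back
#' to reflectance; the continuum-removed reflectance matrix is reduced by
#' PCA to the components explaining more than `var_threshold` of the
#' spectral variation; and [kennard_stone()] selects
#' `round(fraction * n)` training samples in the normalized score space.
#' The split is fully deterministic.
#'
#' @param lib a `spectral_library`.
#' @param fraction training fraction (default two thirds).
#' @param var_threshold PCA explained-variance threshold.
#' @param splice_nm detector splice wavelength.
#' @return A `selection_result` (see [kennard_stone()]) with an added
#'   `pca` element (the fitted `pca_model`) and `sample_id`.
#' @export
split_library <- function(lib, fraction = 2 / 3, var_threshold = 0.99,
                          splice_nm = 1100) {
  stopifnot(inherits(lib, "spectral_library"))
  n <- nrow(lib$properties)
  if (n < 3) stop("need at least 3 samples to split", call. = FALSE)
  refl <- averaged_reflectance(lib, splice_nm)
  cr <- continuum_remove(refl)
  pca <- pca_fit(cr, var_threshold)
  n_train <- as.integer(round_half_away(fraction * n))
  n_train <- max(2L, min(n_train, n))
  res <- kennard_stone(pca$scores_norm, n_train)
  res$pca <- pca
  res$sample_id <- lib$properties$sample_id
  res
}

# Average scans (no QC removal) -> absorbance -> splice correction ->
# reflectance. Shared by split_library and exploratory analyses.
averaged_reflectance <- function(lib, splice_nm = 1100) {
  aq <- average_scans_qc(lib, threshold = Inf)
  m <- to_absorbance(aq$spectra)
  m <- splice_correct(m, splice_nm)
  to_reflectance(m)
}
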