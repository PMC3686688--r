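#' Test-set validation statistics
#'
#' Computes the standard suite used to judge spectroscopic calibrations.
#' With residuals `e_i = pred_i - obs_i`:
#' * bias: difference between the predicted and observed means;
#' * SEP_-b: standard deviation of the residuals (n-1 denominator), the
#'   standard error of prediction corrected for bias;
#' * RMSEP: `sqrt(mean(e_i^2))`;
#' * RPD: SD of the observations divided by RMSEP;
#' * R2: squared Pearson correlation between observed and predicted
#'   (default), or `1 - SSE/SST` with `r2_method = "ssr"`.
#'
#' Bias and SEP_-b are the two components of the RMSEP through the exact
#' identity `rmsep^2 = bias^2 + sep_b^2 * (n-1)/n`.
#'
#' @param obs observed values (length >= 3, non-constant).
#' @param pred predicted values, same length.
#' @param r2_method `"pearson"` (default) or `"ssr"`.
#' @return An object of class `validation_stats`: list `n`, `sd_obs`,
#'   `bias`, `sep_b`, `rmsep`, `rpd`, `r2`. For a perfect prediction the
#'   RPD is infinite and a warning is raised.
#' @export
prediction_stats <- function(obs, pred, r2_method = c("pearson", "ssr")) {
  r2_method <- match.arg(r2_method)
  obs <- as.numeric(obs); pred <- as.numeric(pred)
  n <- length(obs)
  if (length(pred) != n) stop("obs and pred lengths differ", call. = FALSE)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  sd_obs <- stats::sd(obs)
  if (sd_obs == 0)
    stop("constant observations: RPD and R2 undefined", call. = FALSE)
  e <- pred - obs
  bias <- mean(pred) - mean(obs)
  sep_b <- stats::sd(e)
  rmsep <- sqrt(mean(e^2))
  if (rmsep == 0) {
    warning("perfect prediction: RPD is infinite", call. = FALSE)
    rpd <- Inf
  } else rpd <- sd_obs / rmsep
  r2 <- if (r2_method == "pearson") {
    if (stats::sd(pred) == 0) NA_real_ else stats::cor(obs, pred)^2
  } else 1 - sum(e^2) / sum((obs - mean(obs))^2)
  structure(list(n = n, sd_obs = sd_obs, bias = bias, sep_b = sep_b,
                 rmsep = rmsep, rpd = rpd, r2 = r2,
                 r2_method = r2_method),
            class = "validation_stats")
}

#' @export
print.validation_stats <- function(x, ...) {
  cat(sprintf(
    "<validation_stats> n=%d sd=%.4g bias=%.4g sep_b=%.4g rmsep=%.4g rpd=%.4g r2=%.4g\n",
    x$n, x$sd_obs, x$bias, x$sep_b, x$rmsep, x$rpd, x$r2))
  invisible(x)
}

#' Standard error of laboratory from duplicate analyses
#'
#' Reproducibility (intermediate precision) estimated from duplicate
#' measurements: `SEL = sqrt(sum(eps_i^2) / (2 n))` where `eps_i` is the
#' difference between the two replicate values of sample `i`. SEL is zero
#' iff every pair is identical, and is a consistent estimator of the
#' replicate noise SD.
#'
#' @param pairs two-column matrix or data.frame of replicate values, one
#'   row per sample; both entries must be present.
#' @return SEL (same unit as the measurements).
#' @export
sel_from_duplicates <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2)
    stop("pairs must have exactly two replicate columns", call. = FALSE)
  if (nrow(pairs) < 1) stop("need at least one pair", call. = FALSE)
  if (anyNA(pairs))
    stop("unpaired entries: every sample needs both replicates",
         call. = FALSE)
  eps <- pairs[, 1] - pairs[, 2]
  sqrt(sum(eps^2) / (2 * nrow(pairs)))
}

#' Relative RMSEP per SOC x covariate class
#'
#' Bins the test samples jointly by observed SOC and a covariate (for
#' example sand content) and reports, per cell, the RMSEP divided by the
#' mean observed SOC in the cell. Cells with fewer than `min_n` samples
#' are reported with their counts and an undefined (NA) relative RMSEP:
#' emptiness is data, not an error.
#'
#' @param obs observed SOC values.
#' @param pred predictions, same length.
#' @param soc_bins numeric bin edges covering the observed SOC values.
#' @param covariate covariate vector, same length.
#' @param cov_bins numeric bin edges covering the covariate.
#' @param min_n minimal cell size for a defined statistic.
#' @return data.frame `soc_bin`, `cov_bin`, `n`, `mean_obs`, `rmsep`,
#'   `relative_rmsep`.
#' @export
relative_rmsep_by_class <- function(obs, pred, soc_bins, covariate, cov_bins,
                                    min_n = 3) {
  stopifnot(length(obs) == length(pred), length(obs) == length(covariate))
  sb <- cut(obs, soc_bins, include.lowest = TRUE)
  cb <- cut(covariate, cov_bins, include.lowest = TRUE)
  if (anyNA(sb) || anyNA(cb))
    stop("bins do not cover the data", call. = FALSE)
  out <- expand.grid(soc_bin = levels(sb), cov_bin = levels(cb),
                     stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(out)), function(i) {
    in_cell <- sb == out$soc_bin[i] & cb == out$cov_bin[i]
    n <- sum(in_cell)
    if (n < min_n)
      return(data.frame(n = n, mean_obs = NA_real_, rmsep = NA_real_,
                        relative_rmsep = NA_real_))
    m <- mean(obs[in_cell])
    r <- sqrt(mean((pred[in_cell] - obs[in_cell])^2))
    data.frame(n = n, mean_obs = m, rmsep = r, relative_rmsep = r / m)
  })
  cbind(out, do.call(rbind, res))
}

#' Performance report across calibration models
#'
#' One row per model with the columns conventional for spectroscopic
#' calibration reports: Subset, Treatment, Family, Predictor, SD, RMSEP,
#' Bias, SEP-b, RPD, R2, N. SD through SEP-b are rounded to one decimal
#' and RPD/R2 to two, halves away from zero.
#'
#' @param models list of [train_model()] results.
#' @return data.frame in report layout.
#' @export
performance_table <- function(models) {
  if (inherits(models, "calibration_model")) models <- list(models)
  rows <- lapply(models, function(m) {
    s <- m$stats
    data.frame(
      Subset = m$subset,
      Treatment = m$pretreatment,
      Family = m$family$name,
      Predictor = paste0(if (m$predictor$source == "rfe") "rfe" else "spc",
                         if (m$predictor$auxiliary != "none")
                           paste0("+", m$predictor$auxiliary) else ""),
      SD = round_to(s$sd_obs, 1),
      RMSEP = round_to(s$rmsep, 1),
      Bias = round_to(s$bias, 1),
      `SEP-b` = round_to(s$sep_b, 1),
      RPD = round_to(s$rpd, 2),
      R2 = round_to(s$r2, 2),
      N = s$n,
      check.names = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Round half away from zero
#'
#' Decimal rounding with halves away from zero (2.615 -> 2.62), the
#' convention used in the printed reports, rather than IEEE half-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_to <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
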