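#' Reflectance / absorbance conversion
#'
#' Apparent absorbance is `A = log10(1/R)`; the two conversions are exact
#' inverses of each other.
#'
#' @param m a [spectra_matrix()] in reflectance (`to_absorbance`) or
#'   absorbance (`to_reflectance`) mode.
#' @return A [spectra_matrix()] in the converted mode.
#' @export
to_absorbance <- function(m) {
  stopifnot(inherits(m, "spectra_matrix"))
  if (m$mode != "reflectance")
    stop("to_absorbance expects a reflectance matrix", call. = FALSE)
  if (any(m$values <= 0))
    stop("reflectance must be strictly positive", call. = FALSE)
  sm_step(m, log10(1 / m$values), "absorbance", "to_absorbance")
}

#' @rdname to_absorbance
#' @export
to_reflectance <- function(m) {
  stopifnot(inherits(m, "spectra_matrix"))
  if (m$mode != "absorbance")
    stop("to_reflectance expects an absorbance matrix", call. = FALSE)
  sm_step(m, 10^(-m$values), "reflectance", "to_reflectance")
}

#' Average replicate scans with between-scan quality control
#'
#' For each sample the replicate scans are averaged into one reflectance
#' spectrum. Quality control follows laboratory practice for duplicate
#' scans: the per-band standard deviation between scans is computed on the
#' absorbance scale, averaged over all bands, and samples whose mean SD
#' exceeds `threshold` (default 0.01 absorbance) are flagged as improperly
#' measured and excluded from the returned matrix. Samples with a single
#' scan cannot be checked; they are passed through with a warning note in
#' the report.
#'
#' @param lib a `spectral_library` (scans in reflectance).
#' @param threshold QC threshold on the scan-averaged absorbance SD.
#' @return list with `spectra` (a reflectance [spectra_matrix()] of the
#'   retained samples) and `qc` (data.frame `sample_id`, `mean_sd`,
#'   `removed`, `note`).
#' @export
average_scans_qc <- function(lib, threshold = 0.01) {
  stopifnot(inherits(lib, "spectral_library"))
  ids <- lib$properties$sample_id
  n <- length(ids)
  mean_sd <- numeric(n)
  note <- character(n)
  avg <- matrix(0, n, length(lib$wavelengths))
  for (i in seq_len(n)) {
    sc <- lib$scans[[i]]
    avg[i, ] <- colMeans(sc)
    if (nrow(sc) < 2) {
      mean_sd[i] <- NA_real_
      note[i] <- "single scan: QC not applicable"
      warning(sprintf("sample %s has a single scan; QC skipped", ids[i]),
              call. = FALSE)
    } else {
      A <- log10(1 / sc)
      ns <- nrow(A)
      sd_band <- sqrt(pmax(colSums(A^2) - ns * colMeans(A)^2, 0) / (ns - 1))
      mean_sd[i] <- mean(sd_band)
    }
  }
  removed <- !is.na(mean_sd) & mean_sd > threshold
  qc <- data.frame(sample_id = ids, mean_sd = mean_sd, removed = removed,
                   note = note, stringsAsFactors = FALSE)
  keep <- which(!removed)
  v <- avg[keep, , drop = FALSE]
  rownames(v) <- ids[keep]
  spectra <- spectra_matrix(v, lib$wavelengths, "reflectance",
                            provenance = list(list(op = "average_scans_qc",
                                                   threshold = threshold,
                                                   n_removed = sum(removed))))
  list(spectra = spectra, qc = qc)
}

#' Correct the absorbance step at the detector splice
#'
#' Spectrometers combining two detectors show a step discontinuity at the
#' splice wavelength. Per sample, an additive offset is applied to all
#' bands at or beyond `splice_nm` so that the first long-wavelength value
#' equals the linear extrapolation of the last two short-wavelength
#' values; bands below the splice are unchanged. A spectrum that is
#' locally linear and continuous at the splice is left untouched.
#'
#' @param m an absorbance [spectra_matrix()].
#' @param splice_nm splice wavelength (nm); must be strictly inside the
#'   grid with at least two bands below it.
#' @return Corrected [spectra_matrix()].
#' @export
splice_correct <- function(m, splice_nm = 1100) {
  stopifnot(inherits(m, "spectra_matrix"))
  w <- m$wavelengths
  i <- which(w >= splice_nm)[1]
  if (is.na(i) || i < 3 || i > length(w))
    stop("splice_nm must lie strictly inside the grid with >= 2 bands below",
         call. = FALSE)
  v <- m$values
  extrap <- v[, i - 1] + (v[, i - 1] - v[, i - 2]) /
    (w[i - 1] - w[i - 2]) * (w[i] - w[i - 1])
  offset <- v[, i] - extrap
  v[, i:ncol(v)] <- v[, i:ncol(v)] - offset
  sm_step(m, v, m$mode, "splice_correct", list(splice_nm = splice_nm))
}

#' Trim short-wavelength bands
#'
#' Drops all bands with wavelength below `min_nm` (the start of the
#' visible range is affected by instrumental artifacts). On the default
#' 4200-band grid, `min_nm = 500` leaves 4000 bands.
#'
#' @param m a [spectra_matrix()].
#' @param min_nm first wavelength to keep (nm).
#' @return Trimmed [spectra_matrix()].
#' @export
trim_spectra <- function(m, min_nm = 500) {
  stopifnot(inherits(m, "spectra_matrix"))
  keep <- m$wavelengths >= min_nm
  if (!any(keep)) stop("trim would drop every band", call. = FALSE)
  v <- m$values[, keep, drop = FALSE]
  sm_step(m, v, m$mode, "trim", list(min_nm = min_nm),
          wavelengths = m$wavelengths[keep])
}

# Cache of Savitzky-Golay filter matrices keyed by (n_bands, window,
# polyorder, deriv); building the sparse banded matrix once makes the
# filter a single sparse matrix product per call.
.sg_cache <- new.env(parent = emptyenv())

sg_filter_matrix <- function(n_bands, window, polyorder, deriv) {
  key <- paste(n_bands, window, polyorder, deriv, sep = "_")
  if (!is.null(.sg_cache[[key]])) return(.sg_cache[[key]])
  FF <- signal::sgolay(p = polyorder, n = window, m = deriv)
  FF <- unclass(FF)
  h <- (window - 1) / 2
  nwin <- n_bands - window + 1
  # interior: band k (h < k <= n-h) = central row of FF applied to its window
  i <- rep(seq_len(nwin) + h, each = window)
  j <- as.vector(vapply(seq_len(nwin), function(k) k:(k + window - 1),
                        integer(window)))
  Tm <- Matrix::sparseMatrix(i = j, j = i, x = rep(FF[h + 1, ], nwin),
                             dims = c(n_bands, n_bands))
  # edges: evaluate the terminal windows' fitted polynomials off-centre
  for (k in seq_len(h)) {
    Tm[1:window, k] <- FF[k, ]
    Tm[(n_bands - window + 1):n_bands, n_bands - h + k] <- FF[h + 1 + k, ]
  }
  .sg_cache[[key]] <- Tm
  Tm
}

#' Savitzky-Golay smoothing and differentiation
#'
#' Replaces each band by the value (or `deriv`-th derivative) at the
#' window centre of the least-squares polynomial of degree `polyorder`
#' fitted to the surrounding `window` bands. At the spectrum edges the
#' terminal window's polynomial is evaluated at off-centre positions, so
#' the grid keeps its full length. Derivatives are expressed per band
#' step (0.5 nm on the default grid); this unit is recorded in the
#' provenance.
#'
#' @param m a [spectra_matrix()] (any non-reflectance mode; typically
#'   absorbance).
#' @param window odd window length in bands (> `polyorder`).
#' @param polyorder polynomial degree.
#' @param deriv 0 (smoothing) or 1 (first derivative).
#' @return A [spectra_matrix()] in mode `"sg_smoothed"` or
#'   `"sg_first_derivative"`.
#' @export
savitzky_golay <- function(m, window = 101, polyorder = 3, deriv = 0) {
  stopifnot(inherits(m, "spectra_matrix"), deriv %in% c(0, 1))
  if (window %% 2 != 1 || window <= polyorder)
    stop("window must be odd and greater than polyorder", call. = FALSE)
  nb <- ncol(m$values)
  if (window >= nb)
    stop("window must be smaller than the number of bands", call. = FALSE)
  Tm <- sg_filter_matrix(nb, window, polyorder, deriv)
  v <- as.matrix(m$values %*% Tm)
  rownames(v) <- rownames(m$values)
  sm_step(m, v, if (deriv == 0) "sg_smoothed" else "sg_first_derivative",
          "savitzky_golay",
          list(window = window, polyorder = polyorder, deriv = deriv,
               deriv_unit = "per band step"))
}

#' Standard normal variate transformation
#'
#' Centres each spectrum by its own mean and divides by its own standard
#' deviation (n-1 denominator), removing multiplicative scatter effects.
#' Every output row has mean 0 and SD 1; the transform is idempotent.
#'
#' @param m a [spectra_matrix()].
#' @return A [spectra_matrix()] in mode `"snv"`.
#' @export
snv <- function(m) {
  stopifnot(inherits(m, "spectra_matrix"))
  mu <- rowMeans(m$values)
  sdv <- apply(m$values, 1, stats::sd)
  if (any(sdv == 0)) {
    bad <- which(sdv == 0)[1]
    id <- rownames(m$values)[bad]
    stop(sprintf("constant spectrum (sample %s): SNV undefined",
                 if (is.null(id)) as.character(bad) else id), call. = FALSE)
  }
  v <- (m$values - mu) / sdv
  rownames(v) <- rownames(m$values)
  sm_step(m, v, "snv", "snv")
}

#' Keep one band in `factor`
#'
#' Retains bands at positions 1, 1+factor, 1+2*factor, ... of the input
#' grid. With the default chain (4000 bands after trimming, factor 20)
#' this leaves 200 predictor bands at 10 nm spacing.
#'
#' @param m a [spectra_matrix()].
#' @param factor decimation factor (>= 1).
#' @return Decimated [spectra_matrix()].
#' @export
decimate_bands <- function(m, factor = 20) {
  stopifnot(inherits(m, "spectra_matrix"), factor >= 1)
  keep <- seq(1, ncol(m$values), by = factor)
  v <- m$values[, keep, drop = FALSE]
  sm_step(m, v, m$mode, "decimate", list(factor = factor),
          wavelengths = m$wavelengths[keep])
}

# Upper convex hull of (w, r): sorted indices of upper-chain vertices,
# both endpoints included. The full hull comes from grDevices::chull; the
# upper chain is the subset of hull vertices lying strictly above the
# chord joining the two endpoints (orientation-independent).
upper_hull_idx <- function(w, r) {
  n <- length(w)
  if (n < 2) stop("need at least 2 bands", call. = FALSE)
  if (n == 2) return(c(1L, 2L))
  h <- grDevices::chull(w, r)
  cross <- (w[n] - w[1]) * (r[h] - r[1]) - (r[n] - r[1]) * (w[h] - w[1])
  sort(unique(c(1L, n, h[cross > 0])))
}

#' Continuum removal
#'
#' Divides each reflectance spectrum by its upper convex hull (endpoints
#' pinned), so that absorption features become depths below 1: values lie
#' in (0, 1] and hull points map to exactly 1.
#'
#' @param m a reflectance [spectra_matrix()].
#' @return A [spectra_matrix()] in mode `"continuum_removed"`.
#' @export
continuum_remove <- function(m) {
  stopifnot(inherits(m, "spectra_matrix"))
  if (m$mode != "reflectance")
    stop("continuum removal expects a reflectance matrix", call. = FALSE)
  w <- m$wavelengths
  if (length(w) < 2) stop("need at least 2 bands", call. = FALSE)
  v <- m$values
  out <- v
  for (i in seq_len(nrow(v))) {
    idx <- upper_hull_idx(w, v[i, ])
    hull <- stats::approx(w[idx], v[i, idx], xout = w)$y
    cr <- v[i, ] / hull
    cr[idx] <- 1                      # hull vertices map to exactly 1
    out[i, ] <- pmin(cr, 1)
  }
  rownames(out) <- rownames(v)
  sm_step(m, out, "continuum_removed", "continuum_remove")
}

.RECIPES <- c("A", "SG0", "SG1", "SG0+SNV", "SG1+SNV")

#' Build the calibration design matrix from a library
#'
#' Applies the full pre-treatment chain: scan averaging with QC,
#' absorbance conversion, detector-splice correction, trimming of the
#' artifact-prone 400-500 nm region, the named recipe transform
#' (`A` = absorbance only; `SG0`/`SG1` = Savitzky-Golay smoothing / first
#' derivative; optionally followed by SNV), and 1-in-`decimation` band
#' decimation. The full chain is recorded in the provenance.
#'
#' @param lib a `spectral_library`.
#' @param recipe one of `"A"`, `"SG0"`, `"SG1"`, `"SG0+SNV"`, `"SG1+SNV"`.
#' @param qc_threshold between-scan QC threshold (absorbance).
#' @param splice_nm detector splice wavelength (nm).
#' @param trim_nm first wavelength retained (nm).
#' @param window,polyorder Savitzky-Golay settings.
#' @param decimation decimation factor.
#' @return A [spectra_matrix()] with attribute `"qc"` (the QC report).
#' @export
build_design_matrix <- function(lib, recipe = "SG1", qc_threshold = 0.01,
                                splice_nm = 1100, trim_nm = 500,
                                window = 101, polyorder = 3, decimation = 20) {
  if (!recipe %in% .RECIPES)
    stop(sprintf("unknown recipe '%s'; must be one of %s", recipe,
                 paste(.RECIPES, collapse = ", ")), call. = FALSE)
  aq <- average_scans_qc(lib, qc_threshold)
  m <- to_absorbance(aq$spectra)
  m <- splice_correct(m, splice_nm)
  m <- trim_spectra(m, trim_nm)
  if (recipe %in% c("SG0", "SG0+SNV"))
    m <- savitzky_golay(m, window, polyorder, deriv = 0)
  if (recipe %in% c("SG1", "SG1+SNV"))
    m <- savitzky_golay(m, window, polyorder, deriv = 1)
  if (grepl("SNV", recipe, fixed = TRUE)) m <- snv(m)
  m <- decimate_bands(m, decimation)
  attr(m, "qc") <- aq$qc
  m
}
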