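#' Synthetic soil spectral libraries
#'
#' Generators for soil property tables and Vis-NIR spectra with known
#' property-to-spectrum structure, so that every downstream stage of the
#' calibration workflow can be exercised and tested without access to a
#' real library. All generators are pure functions of their arguments and
#' seed (the global RNG state is left untouched).
#'
#' @name synthlib
NULL

# Mineral SOC: lognormal truncated to [0, 200] g/kg. The (meanlog, sdlog)
# pair is the numerical solution for which the TRUNCATED distribution has
# mean 29.4 and sd 28.9 g/kg (right skew ~2.3), matching the summary
# statistics of European mineral topsoils.
.SOC_MINERAL <- list(meanlog = 3.0004844359, sdlog = 0.9399033485,
                     lower = 0, upper = 200)
# Organic SOC: shifted/scaled Beta on [156.4, 586.8] g/kg with shape
# parameters moment-matched to mean 387.1, sd 101.2 (mild negative skew).
.SOC_ORGANIC <- list(lower = 156.4, upper = 586.8,
                     shape1 = 1.8752, shape2 = 1.6232)
# Texture composition: Dirichlet with mean (clay, silt, sand) =
# (18.9, 38.2, 42.9)% and precision 6 (sd ~15-19%, compromise between the
# printed clay and sand spreads; a single Dirichlet cannot match both).
.TEXTURE_ALPHA <- 6 * c(clay = 0.189, silt = 0.382, sand = 0.429)

.SUBSETS <- c("cropland", "grassland", "woodland", "mineral", "organic")

#' Sample a soil property table
#'
#' Draws `n` samples of the laboratory property schema (SOC, total
#' nitrogen, clay/silt/sand, CaCO3, pH, CEC) for a given library subset.
#' Mineral SOC follows a right-skewed truncated lognormal (mean 29.4, SD
#' 28.9 g/kg on \[0, 200\]); organic SOC a scaled Beta on
#' \[156.4, 586.8\] g/kg with mean 387 g/kg and mild negative skew.
#' Textures come from a Dirichlet composition sampler and always sum to
#' 100%; organic samples carry missing textures (particle-size analysis is
#' not performed on organic materials).
#'
#' @param n number of samples (>= 1).
#' @param subset one of `"cropland"`, `"grassland"`, `"woodland"`
#'   (mineral soils under that land cover), `"mineral"` (mixed land
#'   covers) or `"organic"`.
#' @param seed integer seed; the function is deterministic under
#'   `(n, subset, seed)`.
#' @return data.frame with columns `sample_id`, `land_cover`, `material`,
#'   `soc`, `nitrogen`, `clay`, `silt`, `sand`, `caco3`, `ph`, `cec`.
#' @export
sample_properties <- function(n, subset, seed) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  n <- as.integer(n)
  if (!is.character(subset) || length(subset) != 1 || !subset %in% .SUBSETS)
    stop(sprintf("unknown subset '%s'; must be one of %s",
                 paste(subset, collapse = ","),
                 paste(.SUBSETS, collapse = ", ")), call. = FALSE)
  withr::with_seed(as.integer(seed), {
    organic <- subset == "organic"
    if (organic) {
      p <- .SOC_ORGANIC
      soc <- p$lower + (p$upper - p$lower) * stats::rbeta(n, p$shape1, p$shape2)
      nitrogen <- pmax(0.04 * soc + stats::rnorm(n, 0, 2), 0.1)
      clay <- silt <- sand <- rep(NA_real_, n)
      caco3 <- ifelse(stats::runif(n) < 0.7, 0,
                      stats::rlnorm(n, meanlog = 0.5, sdlog = 1.2))
      ph <- pmin(pmax(stats::rnorm(n, 4.5, 0.7), 3.2), 7.5)
      cec <- stats::rgamma(n, shape = 1.62, scale = 25.9)
      land_cover <- sample(c("grassland", "woodland", "other"), n,
                           replace = TRUE, prob = c(0.25, 0.45, 0.30))
    } else {
      p <- .SOC_MINERAL
      u <- stats::runif(n) * stats::plnorm(p$upper, p$meanlog, p$sdlog)
      soc <- stats::qlnorm(u, p$meanlog, p$sdlog)
      g <- cbind(stats::rgamma(n, .TEXTURE_ALPHA[1]),
                 stats::rgamma(n, .TEXTURE_ALPHA[2]),
                 stats::rgamma(n, .TEXTURE_ALPHA[3]))
      tex <- 100 * g / rowSums(g)
      clay <- tex[, 1]; silt <- tex[, 2]; sand <- tex[, 3]
      nitrogen <- pmax(0.07 * soc + stats::rnorm(n, 0, 0.5), 0.05)
      caco3 <- pmin(stats::rlnorm(n, meanlog = 1.5, sdlog = 2.2), 944)
      ph <- pmin(pmax(stats::rnorm(n, 6.3, 1.3), 3.4), 10.1)
      cec <- pmax(0.35 * clay + 0.25 * soc + stats::rnorm(n, 0, 3), 0.1)
      land_cover <- if (subset == "mineral")
        sample(c("cropland", "grassland", "woodland", "other"), n,
               replace = TRUE, prob = c(0.46, 0.23, 0.28, 0.03))
      else rep(subset, n)
    }
    data.frame(
      sample_id = sprintf("%s_%05d", substr(subset, 1, 3), seq_len(n)),
      land_cover = land_cover,
      material = if (organic) "organic" else "mineral",
      soc = soc, nitrogen = nitrogen,
      clay = clay, silt = silt, sand = sand,
      caco3 = caco3, ph = ph, cec = cec,
      stringsAsFactors = FALSE
    )
  })
}

#' Classify a sample as mineral or organic soil material
#'
#' Applies a clay-dependent SOC threshold in the spirit of the FAO
#' definition of organic soil materials: the threshold rises linearly from
#' 120 g C/kg at 0% clay to 180 g C/kg at 60% clay (and stays at 180
#' above); missing clay uses the 120 g/kg floor. A sample is organic iff
#' its SOC is at or above the threshold.
#'
#' @param soc SOC in g C per kg (vectorized, >= 0).
#' @param clay clay content in % (may be `NA`).
#' @return character vector, `"mineral"` or `"organic"`.
#' @export
classify_organic <- function(soc, clay = NA_real_) {
  if (any(soc < 0, na.rm = TRUE) || anyNA(soc))
    stop("soc must be non-negative and non-missing", call. = FALSE)
  clay <- rep_len(clay, length(soc))
  thr <- 120 + 60 * pmin(ifelse(is.na(clay), 0, clay), 60) / 60
  ifelse(soc >= thr, "organic", "mineral")
}

# Deterministic part of the forward model: n x n_bands absorbance matrix
# from a property data.frame (no noise, no splice handling flag).
absorbance_model <- function(props, catalog, wavelengths) {
  n <- nrow(props)
  nb <- length(wavelengths)
  bl <- catalog$baseline
  sand <- props$sand
  clay <- props$clay
  if (anyNA(sand)) sand <- ifelse(is.na(sand), 0, sand)
  if (anyNA(clay)) clay <- ifelse(is.na(clay), 0, clay)
  base_wl <- bl$intercept +
    bl$slope * (wavelengths - wavelengths[1]) /
      (wavelengths[nb] - wavelengths[1])
  A <- matrix(base_wl, n, nb, byrow = TRUE) + bl$sand_scatter * sand / 100
  bands <- catalog$bands
  G <- vapply(seq_len(nrow(bands)), function(b)
    exp(-((wavelengths - bands$center[b])^2) / (2 * bands$width[b]^2)),
    numeric(nb))
  depth <- vapply(seq_len(nrow(bands)), function(b) {
    drv <- bands$driver[b]
    if (!drv %in% names(props))
      stop(sprintf("band driver '%s' is not a property column", drv),
           call. = FALSE)
    val <- props[[drv]]
    val <- ifelse(is.na(val), 0, val)
    d <- bands$gain[b] * val
    if (drv == "soc" && abs(bands$center[b] - 620) < 1)
      d <- d / (1 + bl$clay_mask * clay / 100)  # clay masking of the SOC feature
    d
  }, numeric(n))
  depth <- matrix(depth, nrow = n)
  A <- A + depth %*% t(G)
  A + bl$splice_offset * matrix(wavelengths >= bl$splice_nm, n, nb,
                                byrow = TRUE)
}

check_property_support <- function(props) {
  if (any(props$soc < 0, na.rm = TRUE))
    stop("soc outside generator support (must be >= 0)", call. = FALSE)
  tex <- c(props$clay, props$silt, props$sand)
  if (any(tex < 0 | tex > 100, na.rm = TRUE))
    stop("texture fractions outside generator support ([0, 100]%)",
         call. = FALSE)
  invisible(TRUE)
}

#' Simulate reflectance scans for one sample
#'
#' Builds the absorbance spectrum `baseline + sum(gain * property *
#' Gaussian)` (with sand path-length enhancement and clay masking of the
#' 620 nm feature), adds the detector-splice offset and independent
#' per-scan noise, and converts to reflectance `R = 10^-A` clipped to
#' (0, 1]. The continuum-removed depth of the 620 nm feature increases
#' strictly with SOC and is attenuated as clay increases.
#'
#' @param props one-row data.frame with the property schema of
#'   [sample_properties()].
#' @param catalog a [band_catalog()].
#' @param seed integer seed for the scan noise.
#' @param n_scans number of replicate scans (>= 1).
#' @param wavelengths wavelength grid (nm).
#' @return numeric matrix `n_scans x n_bands` of reflectance.
#' @export
spectrum_from_properties <- function(props, catalog = band_catalog(),
                                     seed = 1L, n_scans = 2,
                                     wavelengths = default_wavelengths()) {
  stopifnot(is.data.frame(props), nrow(props) == 1, n_scans >= 1)
  check_property_support(props)
  A0 <- absorbance_model(props, catalog, wavelengths)
  sand <- if (is.na(props$sand)) 0 else props$sand
  sd_scan <- catalog$noise$scan_sd + catalog$noise$scan_sd_sand * sand / 100
  withr::with_seed(as.integer(seed), {
    scans <- matrix(rep(A0, each = n_scans), n_scans, length(wavelengths))
    if (sd_scan > 0)
      scans <- scans + matrix(stats::rnorm(length(scans), 0, sd_scan),
                              n_scans, length(wavelengths))
    scans <- pmax(scans, 0)        # keep reflectance <= 1
    10^(-scans)
  })
}

#' Generate a synthetic spectral library
#'
#' Composes [sample_properties()] and the forward spectral model into a
#' complete library: per-sample replicate reflectance scans on a shared
#' wavelength grid, plus laboratory SOC analyses. The spectra are driven
#' by the true SOC; the recorded SOC of every sample is one laboratory
#' analysis of it (true value plus the catalog's lab noise), and a
#' fraction of the samples carry a second, independent replicate
#' analysis. The difference between the two analyses of a duplicate
#' sample therefore has standard deviation `lab_sd * sqrt(2)`, so the
#' standard error of laboratory computed from the pairs estimates
#' `lab_sd` consistently.
#'
#' @param n number of samples.
#' @param subset library subset (see [sample_properties()]).
#' @param seed integer seed; the library is deterministic under all
#'   arguments plus `seed`.
#' @param duplicate_fraction fraction in \[0, 1\] of samples that receive a
#'   duplicate laboratory SOC value (`ceiling(duplicate_fraction * n)`
#'   samples, chosen at random).
#' @param catalog a [band_catalog()].
#' @param wavelengths wavelength grid (nm).
#' @param n_scans replicate scans per sample.
#' @return An object of class `spectral_library`: list with `properties`
#'   (data.frame), `wavelengths`, `scans` (list of `n_scans x n_bands`
#'   reflectance matrices, named by sample id) and `duplicates`
#'   (data.frame `sample_id`, `soc_rep`, or NULL).
#' @export
generate_library <- function(n, subset, seed, duplicate_fraction = 0,
                             catalog = band_catalog(),
                             wavelengths = default_wavelengths(),
                             n_scans = 2) {
  stopifnot(duplicate_fraction >= 0, duplicate_fraction <= 1)
  props <- sample_properties(n, subset, seed)
  check_property_support(props)
  A0 <- absorbance_model(props, catalog, wavelengths)
  nb <- length(wavelengths)
  sand <- props$sand
  sand[is.na(sand)] <- 0
  sd_scan <- catalog$noise$scan_sd + catalog$noise$scan_sd_sand * sand / 100
  soc_bounds <- if (subset == "organic")
    c(.SOC_ORGANIC$lower, .SOC_ORGANIC$upper)
  else c(.SOC_MINERAL$lower, .SOC_MINERAL$upper)
  withr::with_seed(as.integer(seed) + 1L, {
    scans <- lapply(seq_len(n), function(i) {
      s <- matrix(rep(A0[i, ], each = n_scans), n_scans, nb)
      if (sd_scan[i] > 0)
        s <- s + matrix(stats::rnorm(n_scans * nb, 0, sd_scan[i]), n_scans, nb)
      10^(-pmax(s, 0))
    })
    names(scans) <- props$sample_id
    lab_sd <- catalog$noise$lab_sd
    soc_true <- props$soc
    if (lab_sd > 0)  # recorded SOC is one lab analysis of the true value
      props$soc <- pmin(pmax(soc_true + stats::rnorm(n, 0, lab_sd),
                             soc_bounds[1]), soc_bounds[2])
    duplicates <- NULL
    n_dup <- ceiling(duplicate_fraction * n)
    if (n_dup > 0) {
      idx <- sort(sample(n, n_dup))
      duplicates <- data.frame(
        sample_id = props$sample_id[idx],
        soc_rep = pmin(pmax(soc_true[idx] +
                              stats::rnorm(n_dup, 0, lab_sd),
                            soc_bounds[1]), soc_bounds[2]),
        stringsAsFactors = FALSE)
    }
    structure(list(properties = props, wavelengths = wavelengths,
                   scans = scans, duplicates = duplicates),
              class = "spectral_library")
  })
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("<spectral_library> %d samples (%s), %d bands, %d scan(s)/sample",
              nrow(x$properties),
              paste(unique(x$properties$material), collapse = "+"),
              length(x$wavelengths), nrow(x$scans[[1]])))
  if (!is.null(x$duplicates))
    cat(sprintf(", %d lab duplicates", nrow(x$duplicates)))
  cat("\n")
  invisible(x)
}

#' Subset a spectral library by sample
#'
#' @param lib a `spectral_library`.
#' @param idx integer indices or character sample ids to keep.
#' @return A `spectral_library` with the selected samples.
#' @export
subset_library <- function(lib, idx) {
  stopifnot(inherits(lib, "spectral_library"))
  if (is.character(idx)) idx <- match(idx, lib$properties$sample_id)
  if (anyNA(idx)) stop("unknown sample id in subset_library", call. = FALSE)
  dup <- lib$duplicates
  if (!is.null(dup))
    dup <- dup[dup$sample_id %in% lib$properties$sample_id[idx], , drop = FALSE]
  structure(list(properties = lib$properties[idx, , drop = FALSE],
                 wavelengths = lib$wavelengths,
                 scans = lib$scans[idx],
                 duplicates = dup),
            class = "spectral_library")
}
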