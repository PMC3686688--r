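#' Absorption-band catalog for the synthetic spectral library
#'
#' The catalog defines the forward model mapping soil properties to an
#' absorbance spectrum: a set of Gaussian absorption bands, each driven by
#' one property; a baseline model (albedo intercept, gentle wavelength
#' slope, sand-driven scattering that both raises the baseline and
#' lengthens the optical path, clay masking of the organic-carbon feature,
#' and a detector-splice offset); and a noise model (between-scan noise in
#' absorbance, laboratory replicate noise on SOC).
#'
#' The default catalog emulates the diagnostic features of continental
#' soil Vis-NIR libraries: a broad organic-carbon feature centred at
#' 620 nm; clay-lattice and hygroscopic-water bands at 1415, 1455, 1915
#' and 2207 nm; and weak iron-oxide features at 540, 640 and 900 nm
#' (driven here by clay, a proxy for the fine fraction that carries the
#' oxides). Sand increases light scattering: the baseline absorbance
#' rises with sand, and the longer optical path deepens the 620 nm
#' organic feature — represented as a sand-driven band co-located with
#' the SOC feature (the first-order form of path-length enhancement,
#' expanded at the mean SOC of the library) — so the feature is enhanced
#' in sandy samples at equal SOC and sand acts as a spectral confound of
#' SOC. Clay attenuates the 620 nm SOC feature multiplicatively by
#' `1 / (1 + clay_mask * clay/100)`.
#'
#' @param bands data.frame with columns `center` (nm), `width` (Gaussian
#'   sigma, nm), `driver` (property column name) and `gain` (absorbance per
#'   property unit).
#' @param baseline named list: `intercept` (absorbance), `slope`
#'   (absorbance over the full grid), `sand_scatter` (baseline absorbance
#'   added at sand = 100%), `clay_mask` (attenuation coefficient of the
#'   620 nm SOC feature), `splice_offset` (absorbance step added at and
#'   beyond `splice_nm`), `splice_nm`.
#' @param noise named list: `scan_sd` (between-scan noise sd, absorbance),
#'   `scan_sd_sand` (additional scan noise sd at sand = 100%; 0 disables),
#'   `lab_sd` (sd of laboratory replicate SOC analyses, g C per kg).
#' @return An object of class `band_catalog`.
#' @export
band_catalog <- function(bands = default_bands(),
                         baseline = list(intercept = 0.35, slope = 0.10,
                                         sand_scatter = 0.15,
                                         clay_mask = 2.0,
                                         splice_offset = 0.05,
                                         splice_nm = 1100),
                         noise = list(scan_sd = 0.002, scan_sd_sand = 0,
                                      lab_sd = 2.0)) {
  bands <- as.data.frame(bands)
  need <- c("center", "width", "driver", "gain")
  if (!all(need %in% names(bands)))
    stop("`bands` needs columns center, width, driver, gain", call. = FALSE)
  if (any(bands$center < 400) || any(bands$center > 2500))
    stop("band centers must lie within [400, 2500] nm", call. = FALSE)
  if (any(bands$width <= 0))
    stop("band widths must be > 0", call. = FALSE)
  if (any(!is.finite(bands$gain)))
    stop("band gains must be finite", call. = FALSE)
  for (nm in c("intercept", "slope", "sand_scatter", "clay_mask",
               "splice_offset", "splice_nm"))
    if (is.null(baseline[[nm]]))
      stop(sprintf("baseline$%s is required", nm), call. = FALSE)
  for (nm in c("scan_sd", "scan_sd_sand", "lab_sd"))
    if (is.null(noise[[nm]]))
      stop(sprintf("noise$%s is required", nm), call. = FALSE)
  structure(list(bands = bands, baseline = baseline, noise = noise),
            class = "band_catalog")
}

#' Default absorption bands
#'
#' @return data.frame of the default Gaussian bands (see [band_catalog()]).
#' @export
default_bands <- function() {
  data.frame(
    center = c(620, 620, 1415, 1455, 1915, 2207, 540, 640, 900),
    width  = c(80,   80,   10,   15,   25,   12,  25,  25,  40),
    driver = c("soc", "sand", "clay", "clay", "clay", "clay", "clay", "clay",
               "clay"),
    gain   = c(0.004, 0.0008, 0.004, 0.003, 0.006, 0.005, 0.0006, 0.0004,
               0.0008),
    stringsAsFactors = FALSE
  )
}

#' Default wavelength grid
#'
#' 400.0 to 2499.5 nm in 0.5 nm steps: 4200 bands.
#' @return numeric vector of wavelengths (nm).
#' @export
default_wavelengths <- function() seq(400, 2499.5, by = 0.5)

#' @export
print.band_catalog <- function(x, ...) {
  cat(sprintf("<band_catalog> %d bands; scan noise sd %.4g A; lab sd %.3g g/kg\n",
              nrow(x$bands), x$noise$scan_sd, x$noise$lab_sd))
  invisible(x)
}

#' Write and read a band catalog as YAML
#'
#' The catalog serializes to a plain-text YAML file with three top-level
#' keys (`bands`, `baseline`, `noise`) mirroring the [band_catalog()]
#' arguments.
#'
#' @param catalog a [band_catalog()].
#' @param path file path.
#' @return `write_band_catalog` returns `path` invisibly;
#'   `read_band_catalog` returns a `band_catalog`.
#' @export
write_band_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "band_catalog"))
  yaml::write_yaml(list(bands = as.list(catalog$bands),
                        baseline = catalog$baseline,
                        noise = catalog$noise), path)
  invisible(path)
}

#' @rdname write_band_catalog
#' @export
read_band_catalog <- function(path) {
  x <- yaml::read_yaml(path)
  band_catalog(bands = as.data.frame(x$bands, stringsAsFactors = FALSE),
               baseline = x$baseline, noise = x$noise)
}
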