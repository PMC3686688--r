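#' Spectra matrix container
#'
#' A `spectra_matrix` holds a set of spectra sharing one wavelength grid:
#' an `n_samples x n_bands` numeric matrix, the wavelength vector (nm,
#' strictly increasing), a `mode` flag recording the physical scale of the
#' values, and an append-only provenance list recording every operation
#' applied so far with its parameters.
#'
#' @param values numeric matrix, samples in rows, bands in columns. Row
#'   names, when present, are sample identifiers and are preserved by all
#'   operations.
#' @param wavelengths numeric vector of band centres in nm, strictly
#'   increasing, one per column of `values`.
#' @param mode character scalar; one of `"reflectance"`, `"absorbance"`,
#'   `"sg_smoothed"`, `"sg_first_derivative"`, `"snv"`,
#'   `"continuum_removed"`. Reflectance and continuum-removed values must
#'   lie in (0, 1].
#' @param provenance list of prior processing steps (each a named list with
#'   at least an `op` element); used internally when deriving one matrix
#'   from another.
#' @return An object of class `spectra_matrix`.
#' @export
spectra_matrix <- function(values, wavelengths,
                           mode = c("reflectance", "absorbance", "sg_smoothed",
                                    "sg_first_derivative", "snv",
                                    "continuum_removed"),
                           provenance = list()) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("spectra must not contain missing or non-finite values", call. = FALSE)
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != ncol(values))
    stop("length(wavelengths) must equal ncol(values)", call. = FALSE)
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (mode %in% c("reflectance", "continuum_removed")) {
    if (any(values <= 0) || any(values > 1 + 1e-12))
      stop(sprintf("%s values must lie in (0, 1]", mode), call. = FALSE)
  }
  structure(list(values = values, wavelengths = wavelengths, mode = mode,
                 provenance = provenance),
            class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("<spectra_matrix> %d samples x %d bands [%s], %.1f-%.1f nm\n",
              nrow(x$values), ncol(x$values), x$mode,
              min(x$wavelengths), max(x$wavelengths)))
  if (length(x$provenance))
    cat("  provenance:", paste(vapply(x$provenance, `[[`, "", "op"),
                               collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.spectra_matrix <- function(x) dim(x$values)

# Derive a new spectra_matrix from `m`, appending one provenance step.
sm_step <- function(m, values, mode, op, params = list(),
                    wavelengths = m$wavelengths) {
  prov <- c(m$provenance, list(c(list(op = op), params)))
  out <- spectra_matrix(values, wavelengths, mode, provenance = prov)
  rownames(out$values) <- rownames(values)
  out
}

#' Subset the samples of a spectra matrix
#'
#' @param m a [spectra_matrix()].
#' @param i row (sample) index vector.
#' @return A `spectra_matrix` with the selected samples, same provenance.
#' @export
sm_subset <- function(m, i) {
  stopifnot(inherits(m, "spectra_matrix"))
  v <- m$values[i, , drop = FALSE]
  out <- spectra_matrix(v, m$wavelengths, m$mode, provenance = m$provenance)
  out
}
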