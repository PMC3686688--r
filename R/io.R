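#' Write a spectral library to CSV
#'
#' One row per (sample, scan): metadata columns (`sample_id`,
#' `land_cover`, `material`, `scan_id`), the property columns (`soc`,
#' `nitrogen`, `clay`, `silt`, `sand`, `caco3`, `ph`, `cec`; missing
#' values as empty cells), then one reflectance column per wavelength
#' named by its nm value with one decimal (`"400.0"`, `"400.5"`, ...).
#' Laboratory duplicate analyses, when present, go to a sibling file
#' `<stem>_duplicates.csv` (`sample_id`, `soc_rep`).
#'
#' @param lib a `spectral_library`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path) {
  stopifnot(inherits(lib, "spectral_library"))
  props <- lib$properties
  n_scans <- vapply(lib$scans, nrow, integer(1))
  meta <- props[rep(seq_len(nrow(props)), n_scans), , drop = FALSE]
  meta$scan_id <- unlist(lapply(n_scans, seq_len))
  spec <- do.call(rbind, lib$scans)
  colnames(spec) <- sprintf("%.1f", lib$wavelengths)
  out <- cbind(meta[, c("sample_id", "land_cover", "material", "scan_id")],
               meta[, c("soc", "nitrogen", "clay", "silt", "sand",
                        "caco3", "ph", "cec")],
               as.data.frame(spec, optional = TRUE))
  data.table::fwrite(out, path, na = "")
  if (!is.null(lib$duplicates))
    data.table::fwrite(lib$duplicates, duplicates_path(path), na = "")
  invisible(path)
}

duplicates_path <- function(path)
  paste0(sub("\\.csv$", "", path), "_duplicates.csv")

.META_COLS <- c("sample_id", "land_cover", "material", "scan_id")
.PROP_COLS <- c("soc", "nitrogen", "clay", "silt", "sand", "caco3", "ph",
                "cec")

#' Read a spectral library from CSV
#'
#' Parses and validates the format written by [write_library()]:
#' wavelength columns must be strictly increasing left to right, every
#' (sample_id, scan_id) pair unique, and all spectral cells numeric;
#' violations are rejected with the offending column or row named. Empty
#' property cells are parsed as missing, not zero.
#'
#' @param path CSV path.
#' @return A `spectral_library`.
#' @export
read_library <- function(path) {
  d <- data.table::fread(path, na.strings = "", data.table = FALSE)
  miss <- setdiff(c(.META_COLS, .PROP_COLS), names(d))
  if (length(miss))
    stop(sprintf("missing required column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  wcols <- setdiff(names(d), c(.META_COLS, .PROP_COLS))
  wl <- suppressWarnings(as.numeric(wcols))
  if (anyNA(wl))
    stop(sprintf("non-numeric wavelength column name '%s'",
                 wcols[which(is.na(wl))[1]]), call. = FALSE)
  bad <- which(diff(wl) <= 0)
  if (length(bad))
    stop(sprintf("wavelength columns not strictly increasing at column '%s'",
                 wcols[bad[1] + 1]), call. = FALSE)
  key <- paste(d$sample_id, d$scan_id)
  if (anyDuplicated(key))
    stop(sprintf("duplicate (sample_id, scan_id) pair: %s",
                 key[anyDuplicated(key)]), call. = FALSE)
  spec <- as.matrix(d[, wcols, drop = FALSE])
  if (!is.numeric(spec)) {
    num <- suppressWarnings(matrix(as.numeric(spec), nrow(spec)))
    bad <- which(is.na(num) & !is.na(spec), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric spectral value in row %d, column '%s'",
                   bad[1, 1], wcols[bad[1, 2]]), call. = FALSE)
    spec <- num
  }
  if (anyNA(spec)) {
    bad_row <- which(rowSums(is.na(spec)) > 0)[1]
    stop(sprintf("missing spectral value in row %d", bad_row), call. = FALSE)
  }
  ids <- unique(d$sample_id)
  props <- d[match(ids, d$sample_id), c(.META_COLS, .PROP_COLS)]
  props$scan_id <- NULL
  rownames(props) <- NULL
  scans <- lapply(ids, function(id) {
    rows <- which(d$sample_id == id)
    rows <- rows[order(d$scan_id[rows])]
    unname(spec[rows, , drop = FALSE])
  })
  names(scans) <- ids
  duplicates <- NULL
  dp <- duplicates_path(path)
  if (file.exists(dp)) {
    duplicates <- data.table::fread(dp, na.strings = "", data.table = FALSE)
    if (!all(c("sample_id", "soc_rep") %in% names(duplicates)))
      stop("duplicates file needs columns sample_id, soc_rep", call. = FALSE)
  }
  structure(list(properties = props, wavelengths = wl, scans = scans,
                 duplicates = duplicates),
            class = "spectral_library")
}

#' Write a selection result to CSV
#'
#' Columns: `sample_id`, `role` (train/test), `selection_rank` (NA for
#' test samples), `maximin_distance`.
#'
#' @param sel a `selection_result` from [split_library()] (needs the
#'   `sample_id` element) or [kennard_stone()] plus `ids`.
#' @param path output CSV path.
#' @param ids sample ids when `sel` lacks them.
#' @return `path`, invisibly.
#' @export
write_selection <- function(sel, path, ids = sel$sample_id) {
  stopifnot(inherits(sel, "selection_result"), !is.null(ids))
  n <- length(ids)
  rank <- match(seq_len(n), sel$order)
  out <- data.frame(sample_id = ids,
                    role = ifelse(seq_len(n) %in% sel$train, "train", "test"),
                    selection_rank = rank,
                    maximin_distance = sel$distance[rank])
  data.table::fwrite(out, path, na = "")
  invisible(path)
}

#' Write a fitted calibration model as a plain-text archive
#'
#' Writes a directory containing `manifest.yaml` (format version,
#' recipes, chosen parameters, seeds), `coefficients.csv` (for PLS-backed
#' fits), `tuning.csv` (grid x partition CV RMSE) and, when present,
#' `rfe.csv`.
#'
#' @param model a [train_model()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_model_archive <- function(model, dir) {
  stopifnot(inherits(model, "calibration_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    format_version = 1L,
    family = model$family$name,
    subset = model$subset,
    pretreatment = model$pretreatment,
    predictor = model$predictor,
    chosen_params = model$chosen$params,
    cv_partitions = ncol(model$tuning$rmse),
    seed = model$seed,
    n_train = length(model$split$train),
    n_test = length(model$split$test))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  if (!is.null(model$fit$coefficients))
    data.table::fwrite(data.frame(index = seq_along(model$fit$coefficients),
                                  coefficient = model$fit$coefficients),
                       file.path(dir, "coefficients.csv"))
  tune <- data.frame(complexity = model$tuning$complexity,
                     mean_rmse = model$tuning$mean, se = model$tuning$se)
  data.table::fwrite(tune, file.path(dir, "tuning.csv"))
  if (!is.null(model$rfe))
    data.table::fwrite(data.frame(size = model$rfe$sizes,
                                  cv_mean = model$rfe$cv_mean,
                                  cv_se = model$rfe$cv_se),
                       file.path(dir, "rfe.csv"))
  invisible(dir)
}
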