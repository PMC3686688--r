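#' Validate a run configuration
#'
#' A run configuration is a named list (typically read from a YAML file)
#' describing one end-to-end run. Recognized fields, with defaults in
#' brackets:
#' * `subset` ["mineral"]: library subset;
#' * `n_samples` [300] and `simulate` [TRUE], or `library` (path to a
#'   library CSV);
#' * `duplicate_fraction` [0];
#' * `pretreatment` ["SG1"];
#' * `predictor`: list with `source` ["spectra"] and `auxiliary` ["none"];
#' * `family` ["pls"]; `max_lv` [20]; `rfe_sizes` [all/100/50/25/10];
#' * `ks_fraction` [2/3]; `qc_threshold` [0.01]; `n_partitions` [10];
#' * `seed` [1]; `output_dir` (required).
#'
#' Validation is fail-fast with field-level messages; invalid
#' combinations (for example auxiliary predictors on the organic subset)
#' are rejected before any computation.
#'
#' @param config named list or path to a YAML file.
#' @return The completed configuration (defaults filled in).
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  defaults <- list(subset = "mineral", n_samples = 300, simulate = TRUE,
                   duplicate_fraction = 0, pretreatment = "SG1",
                   predictor = list(source = "spectra", auxiliary = "none"),
                   family = "pls", max_lv = 20, rfe_sizes = NULL,
                   ks_fraction = 2 / 3, qc_threshold = 0.01,
                   n_partitions = 10, seed = 1L)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  fail <- function(field, msg)
    stop(sprintf("config field '%s': %s", field, msg), call. = FALSE)
  if (is.null(config$output_dir) || !is.character(config$output_dir))
    fail("output_dir", "required (character path)")
  if (!config$subset %in% c("mineral", "organic", "cropland", "grassland",
                            "woodland", "all"))
    fail("subset", sprintf("unknown value '%s'", config$subset))
  if (!config$pretreatment %in% .RECIPES)
    fail("pretreatment", sprintf("unknown recipe '%s'", config$pretreatment))
  if (!isTRUE(config$simulate) && is.null(config$library))
    fail("library", "required when simulate is false")
  if (isTRUE(config$simulate) &&
      (!is.numeric(config$n_samples) || config$n_samples < 3))
    fail("n_samples", "must be numeric >= 3")
  if (!is.numeric(config$seed)) fail("seed", "must be an integer")
  if (!is.numeric(config$ks_fraction) || config$ks_fraction <= 0 ||
      config$ks_fraction >= 1)
    fail("ks_fraction", "must lie in (0, 1)")
  if (!is.numeric(config$qc_threshold) || config$qc_threshold < 0)
    fail("qc_threshold", "must be a non-negative number")
  if (!config$family %in% c("pls", "rf"))
    fail("family", sprintf("unknown family '%s'", config$family))
  p <- config$predictor
  if (!is.list(p) || is.null(p$source) || is.null(p$auxiliary))
    fail("predictor", "must be a list with source and auxiliary")
  if (!p$source %in% c("spectra", "rfe"))
    fail("predictor.source", sprintf("unknown source '%s'", p$source))
  if (!p$auxiliary %in% c("none", "sand", "clay", "both"))
    fail("predictor.auxiliary", sprintf("unknown value '%s'", p$auxiliary))
  if (config$subset == "organic" && p$auxiliary != "none")
    fail("predictor.auxiliary",
         "auxiliary particle-size predictors are unavailable for organic samples")
  config
}

#' Run the full calibration pipeline from a configuration
#'
#' Executes simulate (optional) -> preprocess -> split -> calibrate ->
#' validate, writing all artifacts under `output_dir`: `qc_report.csv`,
#' `selection.csv`, a plain-text model archive under `model/`,
#' `validation_stats.csv`, `predictions.csv`, `config_used.yaml` and a
#' timestamped key=value `run.log`. Statistics files contain no
#' timestamps, so identical configurations yield byte-identical reports.
#'
#' @param config named list or YAML path (see [validate_run_config()]).
#' @return The fitted `calibration_model`, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_run_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(cfg$output_dir, "run.log")
  logline <- function(level, stage, ...) {
    kv <- paste(..., sep = " ")
    cat(sprintf("%s level=%s stage=%s %s\n",
                format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), level, stage, kv),
        file = logfile, append = TRUE)
  }
  run_stage <- function(stage, expr) {
    logline("info", stage, "status=start")
    out <- tryCatch(expr, error = function(e) {
      logline("error", stage, sprintf("status=failed message=%s",
                                      conditionMessage(e)))
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    logline("info", stage, "status=done")
    out
  }
  lib <- run_stage("simulate", {
    if (isTRUE(cfg$simulate))
      generate_library(cfg$n_samples, cfg$subset, seed = cfg$seed,
                       duplicate_fraction = cfg$duplicate_fraction)
    else read_library(cfg$library)
  })
  logline("info", "simulate", sprintf("seed=%d n=%d subset=%s",
                                      as.integer(cfg$seed),
                                      nrow(lib$properties), cfg$subset))
  family <- switch(cfg$family, pls = pls_family(), rf = rf_family())
  grid <- if (cfg$family == "pls") pls_grid(cfg$max_lv)
          else lapply(c(2, 5, 10), function(m) list(mtry = m))
  model <- run_stage("calibrate", {
    train_model(lib,
                subset = if (isTRUE(cfg$simulate)) "all" else cfg$subset,
                pretreatment = cfg$pretreatment,
                predictor = predictor_recipe(cfg$predictor$source,
                                             cfg$predictor$auxiliary),
                family = family, grid = grid, seed = cfg$seed,
                rfe_sizes = cfg$rfe_sizes, ks_fraction = cfg$ks_fraction,
                qc_threshold = cfg$qc_threshold,
                n_partitions = cfg$n_partitions)
  })
  run_stage("report", {
    data.table::fwrite(model$qc, file.path(cfg$output_dir, "qc_report.csv"),
                       na = "")
    write_selection(model$split,
                    file.path(cfg$output_dir, "selection.csv"))
    write_model_archive(model, file.path(cfg$output_dir, "model"))
    s <- model$stats
    data.table::fwrite(data.frame(n = s$n, sd_obs = s$sd_obs, bias = s$bias,
                                  sep_b = s$sep_b, rmsep = s$rmsep,
                                  rpd = s$rpd, r2 = s$r2),
                       file.path(cfg$output_dir, "validation_stats.csv"))
    data.table::fwrite(model$test,
                       file.path(cfg$output_dir, "predictions.csv"))
    if (!is.null(lib$duplicates)) {
      both <- merge(lib$duplicates,
                    lib$properties[, c("sample_id", "soc")], by = "sample_id")
      data.table::fwrite(
        data.frame(n_pairs = nrow(both),
                   sel = sel_from_duplicates(both[, c("soc", "soc_rep")])),
        file.path(cfg$output_dir, "sel.csv"))
    }
    cfg_out <- cfg
    yaml::write_yaml(cfg_out, file.path(cfg$output_dir, "config_used.yaml"))
  })
  logline("info", "pipeline", sprintf("status=complete rmsep=%.6g r2=%.6g",
                                      model$stats$rmsep, model$stats$r2))
  invisible(model)
}
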