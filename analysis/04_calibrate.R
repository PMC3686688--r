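#!/usr/bin/env Rscript
# Calibrate SOC models on a simulated mineral library and a smaller
# organic library: Kennard-Stone split, PLS with 10 half-partition
# cross-validation and one-SE selection, across pre-treatments and
# predictor recipes (spectra only, RFE-selected bands, auxiliary sand).
# Writes the consolidated performance table.

suppressMessages(library(socspec))
dir.create("results", showWarnings = FALSE)

lib <- generate_library(600, "mineral", seed = 11)
runs <- list(
  list(pre = "SG1", rec = predictor_recipe("spectra", "none")),
  list(pre = "SG0", rec = predictor_recipe("spectra", "none")),
  list(pre = "SG1+SNV", rec = predictor_recipe("spectra", "none")),
  list(pre = "SG1", rec = predictor_recipe("spectra", "sand")),
  list(pre = "SG1", rec = predictor_recipe("rfe", "sand"))
)
models <- lapply(runs, function(r) {
  m <- train_model(lib, "mineral", r$pre, r$rec, seed = 17,
                   rfe_sizes = c(200, 50, 25, 10))
  cat(sprintf("mineral | %-7s | %-8s -> RMSEP %5.2f  RPD %4.2f  R2 %4.2f (n_lv %d)\n",
              r$pre, paste0(ifelse(r$rec$source == "rfe", "rfe", "spc"),
                            ifelse(r$rec$auxiliary == "none", "",
                                   paste0("+", r$rec$auxiliary))),
              m$stats$rmsep, m$stats$rpd, m$stats$r2,
              m$chosen$params$n_lv))
  m
})

# Note: SNV is deliberately absent from the organic run. In the synthetic
# world the SOC signal dominates the spectral amplitude, and SNV's
# per-spectrum scaling removes exactly that amplitude, collapsing the
# calibration (see the SG1+SNV mineral row above); real libraries carry
# scatter variability that SNV removes instead.
liborg <- generate_library(200, "organic", seed = 12)
morg <- train_model(liborg, "organic", "SG1", seed = 18)
cat(sprintf("organic | SG1     | spc      -> RMSEP %5.2f  RPD %4.2f  R2 %4.2f\n",
            morg$stats$rmsep, morg$stats$rpd, morg$stats$r2))
cat("(the organic RMSEP sits at the ~2 g/kg laboratory noise floor: synthetic\n")
cat(" organic spectra are driven by SOC alone, with no texture confounds --\n")
cat(" real organic materials vary in composition and are far harder)\n")

tab <- performance_table(c(models, list(morg)))
write.csv(tab, "results/model_performance.csv", row.names = FALSE)
cat("\nConsolidated performance table (test-set statistics):\n")
print(tab, row.names = FALSE)

best <- models[[4]]
write_model_archive(best, "results/model_sg1_sand")
write_selection(best$split, "results/selection_sg1_sand.csv")
data.table::fwrite(best$test, "results/predictions_sg1_sand.csv")
cat("\narchived the SG1 + sand model under results/model_sg1_sand/\n")
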