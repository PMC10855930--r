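#!/usr/bin/env Rscript
# FS-MRMR wavelength selection per legume/contaminant pair: 50/25/25
# stratified split, forward addition ranked by the mutual-information
# quotient, stopping when the wrapper classifier's validation accuracy
# reaches the target.
#
# Reads  results/spectra_<pair>.csv   (from 01_simulate_and_extract.R)
# Writes results/selection_<pair>.json and results/selection_summary.csv

library(hypersort)

seed <- 20240126L
res_dir <- "results"
pairs <- sub("^spectra_(.*)\\.csv$", "\\1",
             list.files(res_dir, pattern = "^spectra_.*\\.csv$"))
stopifnot(length(pairs) > 0)

summary_rows <- list()
for (pair in pairs) {
  st <- spectrum_table_from_df(
    read.csv(file.path(res_dir, sprintf("spectra_%s.csv", pair))))
  sp <- split_data(st, rng_seed = seed)
  sel <- forward_select(sp$train, make_svm_wrapper(sp$train, sp$validation),
                        target_ccr = 100)
  jsonlite::write_json(
    list(dataset = pair, selected = sel$selected, stop_reason = sel$stop_reason,
         scores = sel$scores, validation_trace = sel$trace),
    file.path(res_dir, sprintf("selection_%s.json", pair)),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  summary_rows[[pair]] <- data.frame(
    Dataset = pair, Wavelengths = paste(sel$selected, collapse = "; "),
    n_selected = length(sel$selected),
    final_validation_accuracy = round(tail(sel$trace, 1), 2),
    stop_reason = sel$stop_reason)
  message(sprintf("%-18s selected {%s} (%s)", pair,
                  paste(sel$selected, collapse = ", "), sel$stop_reason))
}
write.csv(do.call(rbind, summary_rows),
          file.path(res_dir, "selection_summary.csv"), row.names = FALSE)
message("wrote ", res_dir, "/selection_summary.csv")
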