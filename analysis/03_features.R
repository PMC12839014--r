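#!/usr/bin/env Rscript
# Featurize the curated datasets: the three fingerprints, the 208-descriptor
# block with its train-fitted min-max scaler, and a summary of all seven
# representations. Feature matrices are cheap to recompute, so only the
# scaler parameters and summary tables are persisted.

library(chemsieve)

ds_dir <- file.path("results", "datasets")
out <- file.path("results", "features")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (scheme in c("lo", "po")) {
  train <- utils::read.csv(file.path(ds_dir, paste0(scheme, "_train.csv")),
                           stringsAsFactors = FALSE)
  desc <- calc_descriptors(train$std_key)
  scaler <- fit_minmax(desc)
  jsonlite::write_json(
    list(kind = "descriptors", length = ncol(desc),
         manifest = colnames(desc),
         min = unname(scaler$min), max = unname(scaler$max)),
    file.path(out, paste0(scheme, "_scaler.json")), digits = NA)
  rows <- lapply(names(feature_lengths()), function(kind) {
    X <- featurize(train$std_key[1:25], kind, scaler = scaler)
    data.frame(scheme = toupper(scheme), kind = kind, length = ncol(X),
               density = round(mean(X != 0), 4))
  })
  summary <- do.call(rbind, rows)
  utils::write.csv(summary, file.path(out, paste0(scheme, "_summary.csv")),
                   row.names = FALSE)
  message(paste(capture.output(print(summary, row.names = FALSE)), collapse = "\n"))
}
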