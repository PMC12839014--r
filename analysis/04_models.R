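#!/usr/bin/env Rscript
# Train the model zoo on both schemes: all five algorithms across the seven
# molecular representations (reduced one-point grids for speed; switch
# `tune <- "full"` for the exhaustive grids), rank by test-set MCC, and run
# 5-fold cross-validation on the winner.

library(chemsieve)

seed <- 1L
tune <- "none"
ds_dir <- file.path("results", "datasets")
out <- file.path("results", "models")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

red <- reduced_grids()
rows <- list()
for (scheme in c("LO", "PO")) {
  train <- utils::read.csv(file.path(ds_dir, paste0(tolower(scheme), "_train.csv")),
                           stringsAsFactors = FALSE)
  test <- utils::read.csv(file.path(ds_dir, paste0(tolower(scheme), "_test.csv")),
                          stringsAsFactors = FALSE)
  desc_tr <- calc_descriptors(train$std_key)
  scaler <- fit_minmax(desc_tr)
  for (kind in names(feature_lengths())) {
    Xtr <- featurize(train$std_key, kind, scaler = scaler)
    Xte <- featurize(test$std_key, kind, scaler = scaler)
    for (alg in names(red)) {
      spec <- if (tune == "full")
        grid_search(alg, kind, Xtr, train$label, seed = seed + 303L)$best
      else model_spec(alg, kind, as.list(red[[alg]][1, , drop = FALSE]),
                      seed = seed + 303L)
      model <- fit_final(spec, Xtr, train$label)
      rep_ <- metrics_report(predict_ps(model, Xte), test$label, 0.5)
      rows[[length(rows) + 1L]] <- data.frame(
        scheme = scheme, algorithm = alg, representation = kind,
        mcc = rep_$mcc, precision = rep_$precision, recall = rep_$recall)
      message(sprintf("%s %-4s %-11s test MCC %.3f", scheme, alg, kind, rep_$mcc))
    }
  }
}
ranking <- rank_models(do.call(rbind, rows))
utils::write.csv(ranking, file.path(out, "ranking.csv"), row.names = FALSE)

best <- ranking[1, ]
message(sprintf("best model: %s %s under %s (test MCC %.3f)",
                best$algorithm, best$representation, best$scheme, best$mcc))
jsonlite::write_json(as.list(best), file.path(out, "best_model.json"),
                     auto_unbox = TRUE, digits = NA)

# robustness of the winner across folds
train <- utils::read.csv(file.path(ds_dir, paste0(tolower(best$scheme), "_train.csv")),
                         stringsAsFactors = FALSE)
scaler <- fit_minmax(calc_descriptors(train$std_key))
Xtr <- featurize(train$std_key, best$representation, scaler = scaler)
spec <- model_spec(best$algorithm, best$representation,
                   as.list(red[[best$algorithm]][1, , drop = FALSE]),
                   seed = seed + 303L)
cv <- five_fold_cv(spec, Xtr, train$label, seed = seed + 505L)
message(sprintf("winner 5-fold CV MCC: %.3f +/- %.3f", cv$mean, cv$sd))
jsonlite::write_json(cv, file.path(out, "best_model_cv.json"), digits = NA)
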