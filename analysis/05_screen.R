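#!/usr/bin/env Rscript
# Virtual screening with the selected model: probability-score the library,
# examine the precision/recall threshold sweep on the test set, keep hits
# with PS >= 0.8, cluster them for diversity at distance cutoff 0.30, and
# select one available representative per cluster.

library(chemsieve)

seed <- 1L
ds_dir <- file.path("results", "datasets")
out <- file.path("results", "screening")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

best <- jsonlite::read_json(file.path("results", "models", "best_model.json"),
                            simplifyVector = TRUE)
train <- utils::read.csv(file.path(ds_dir, paste0(tolower(best$scheme), "_train.csv")),
                         stringsAsFactors = FALSE)
test <- utils::read.csv(file.path(ds_dir, paste0(tolower(best$scheme), "_test.csv")),
                        stringsAsFactors = FALSE)
scaler <- fit_minmax(calc_descriptors(train$std_key))
Xtr <- featurize(train$std_key, best$representation, scaler = scaler)
spec <- model_spec(best$algorithm, best$representation,
                   as.list(reduced_grids()[[best$algorithm]][1, , drop = FALSE]),
                   seed = seed + 303L)
model <- fit_final(spec, Xtr, train$label)

sw <- sweep_thresholds(predict_ps(model, featurize(test$std_key, best$representation,
                                                   scaler = scaler)),
                       test$label)
utils::write.csv(sw$curve, file.path(out, "threshold_sweep.csv"), row.names = FALSE)
message(sprintf("smallest threshold with perfect precision: %s",
                format(sw$perfect_precision_threshold)))

library_df <- read_compounds(file.path("results", "data", "screening_library.smi"),
                             "smi")
scored <- score_library(model, library_df, scaler = scaler)
utils::write.csv(scored$scored, file.path(out, "scored_library.csv"),
                 row.names = FALSE)
utils::write.csv(scored$rejects, file.path(out, "reject_log.csv"),
                 row.names = FALSE)

hits <- filter_hits(scored$scored, ps_min = 0.8)
utils::write.csv(hits, file.path(out, "hits.csv"), row.names = FALSE)
message(sprintf("%d / %d compounds scored PS > 0.5; %d hits at PS >= 0.8",
                sum(scored$scored$ps > 0.5), nrow(scored$scored), nrow(hits)))

clusters <- cluster_hits(hits, cut = 0.30)
utils::write.csv(clusters$assignment, file.path(out, "clusters.csv"),
                 row.names = FALSE)
reps <- select_representatives(clusters$assignment, hits)
utils::write.csv(reps$representatives, file.path(out, "representatives.csv"),
                 row.names = FALSE)
message(sprintf("%d clusters at distance cutoff 0.30 -> %d purchased-candidate representatives",
                clusters$n_clusters, nrow(reps$representatives)))
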