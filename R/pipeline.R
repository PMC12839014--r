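# End-to-end orchestration: synthetic data -> curation -> featurization ->
# model zoo -> ranking -> library screening -> diversity clustering. The
# analysis/ scripts and the acceptance script are thin drivers over this.

#' Reduced one-point-per-algorithm hyperparameter grids
#'
#' Default configurations used by the end-to-end pipeline when exhaustive
#' tuning is not requested.
#'
#' @return named list of one-row data.frames.
#' @export
reduced_grids <- function() {
  list(RF = data.frame(trees = 500L, mtry_rule = "sqrt", stringsAsFactors = FALSE),
       SVM = data.frame(kernel = "tanimoto", stringsAsFactors = FALSE),
       KNN = data.frame(k = 5L, weights = "distance", stringsAsFactors = FALSE),
       GP = data.frame(kernel = "rbf", stringsAsFactors = FALSE),
       MLP = data.frame(layers = 2L, width = 100L, batch = 100L, epochs = 20L,
                        stringsAsFactors = FALSE))
}

# compute the building-block features for a compound set once, then assemble
# any representation from them
.cs_feature_bundle <- function(smiles, kinds) {
  need_path <- any(kinds %in% c("path_fp", "hybridRR"))
  need_morgan <- any(kinds %in% c("morgan_fp", "hybridMR"))
  need_dict <- any(kinds %in% c("dict_fp", "hybridPR"))
  need_desc <- any(kinds %in% c("descriptors", "hybridRR", "hybridMR", "hybridPR"))
  list(path = if (need_path) path_fp(smiles),
       morgan = if (need_morgan) morgan_fp(smiles),
       dict = if (need_dict) dict_fp(smiles),
       desc = if (need_desc) calc_descriptors(smiles))
}

.cs_assemble_kind <- function(bundle, kind, scaler = NULL) {
  sdesc <- function() apply_minmax(scaler, bundle$desc)
  switch(kind,
         path_fp = bundle$path,
         morgan_fp = bundle$morgan,
         dict_fp = bundle$dict,
         descriptors = sdesc(),
         hybridRR = hybrid_features(bundle$path, sdesc()),
         hybridMR = hybrid_features(bundle$morgan, sdesc()),
         hybridPR = hybrid_features(bundle$dict, sdesc()))
}

#' Run the full virtual-screening pipeline on synthetic data
#'
#' Generates a synthetic activity table, decoys and a screening library;
#' curates balanced train/test dataset pairs per classification scheme;
#' trains the model zoo over the requested representations (reduced one-point
#' grids by default, exhaustive grid search on request); ranks all models by
#' test MCC; then uses the best model for the screening stage: probability
#' scoring, threshold sweep, hit filtering, diversity clustering and
#' representative selection.
#'
#' @param cfg a [synth_config()] for the activity library.
#' @param seed master seed; every stage derives its own stream from it.
#' @param schemes character vector of scheme names (`"LO"`, `"PO"`).
#' @param algorithms subset of RF, SVM, KNN, GP, MLP.
#' @param representations subset of [feature_lengths()] names.
#' @param tune `"none"` (reduced grids) or `"full"` (exhaustive grid search
#'   per model).
#' @param screen_n size of the synthetic screening library.
#' @param ps_min hit-filter probability-score threshold (inclusive).
#' @param cut clustering distance cutoff.
#' @return list with `datasets`, `ranking`, `models` (per scheme), `best`,
#'   `sweep`, `screening` (scored library, hits, clusters, representatives).
#' @export
run_pipeline <- function(cfg = synth_config(), seed = 1L,
                         schemes = c("LO", "PO"),
                         algorithms = c("RF", "SVM", "KNN", "GP", "MLP"),
                         representations = names(feature_lengths()),
                         tune = c("none", "full"),
                         screen_n = 10000L, ps_min = 0.8, cut = 0.30) {
  tune <- match.arg(tune)
  lib <- generate_library(cfg)
  act <- assign_activities(lib, cfg)
  decoys <- generate_decoys(max(200L, cfg$n_compounds), seed = seed + 101L)
  pairs <- build_datasets(act, decoys,
                          schemes = lapply(schemes, scheme_params),
                          seed = seed + 202L)
  red <- reduced_grids()
  rows <- list(); models <- list(); scalers <- list(); bundles <- list()
  for (sn in names(pairs)) {
    pair <- pairs[[sn]]
    btr <- .cs_feature_bundle(pair$train$std_key, representations)
    bte <- .cs_feature_bundle(pair$test$std_key, representations)
    scaler <- if (!is.null(btr$desc)) fit_minmax(btr$desc)
    scalers[[sn]] <- scaler
    bundles[[sn]] <- list(train = btr, test = bte)
    for (kind in representations) {
      Xtr <- .cs_assemble_kind(btr, kind, scaler)
      Xte <- .cs_assemble_kind(bte, kind, scaler)
      for (alg in algorithms) {
        spec <- if (tune == "full") {
          grid_search(alg, kind, Xtr, pair$train$label, seed = seed + 303L)$best
        } else {
          model_spec(alg, kind, as.list(red[[alg]][1L, , drop = FALSE]),
                     seed = seed + 303L)
        }
        mod <- fit_final(spec, Xtr, pair$train$label)
        ps <- predict_ps(mod, Xte)
        rep_ <- metrics_report(ps, pair$test$label, 0.5)
        models[[paste(sn, alg, kind)]] <- mod
        rows[[length(rows) + 1L]] <- data.frame(
          scheme = sn, algorithm = alg, representation = kind,
          mcc = rep_$mcc, precision = rep_$precision, recall = rep_$recall,
          stringsAsFactors = FALSE)
      }
    }
  }
  ranking <- rank_models(do.call(rbind, rows))
  best_row <- ranking[1L, ]
  best_key <- paste(best_row$scheme, best_row$algorithm, best_row$representation)
  best_model <- models[[best_key]]
  best_pair <- pairs[[best_row$scheme]]
  best_scaler <- scalers[[best_row$scheme]]
  Xte_best <- .cs_assemble_kind(bundles[[best_row$scheme]]$test,
                                best_row$representation, best_scaler)
  ps_test <- predict_ps(best_model, Xte_best)
  sweep <- sweep_thresholds(ps_test, best_pair$test$label)

  screen_cfg <- synth_config(n_compounds = screen_n, seed = seed + 404L,
                             frac_pharmacophore = 0.05,
                             mu_active = cfg$mu_active,
                             mu_inactive = cfg$mu_inactive, sigma = cfg$sigma)
  screen_lib <- generate_library(screen_cfg)
  scored <- score_library(best_model,
                          data.frame(compound_id = screen_lib$compound_id,
                                     smiles = screen_lib$smiles,
                                     stringsAsFactors = FALSE),
                          scaler = best_scaler)
  hits <- filter_hits(scored$scored, ps_min = ps_min)
  clusters <- if (nrow(hits) > 0) cluster_hits(hits, cut = cut) else NULL
  reps <- if (!is.null(clusters)) select_representatives(clusters$assignment, hits)
  list(datasets = pairs, ranking = ranking, models = models,
       best = list(row = best_row, model = best_model, scaler = best_scaler),
       sweep = sweep,
       screening = list(library = screen_lib, scored = scored$scored,
                        rejects = scored$rejects, hits = hits,
                        clusters = clusters,
                        representatives = if (!is.null(reps)) reps$representatives,
                        skipped_clusters = if (!is.null(reps)) reps$skipped_clusters))
}
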