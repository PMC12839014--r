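# Virtual screening: batched probability scoring of a standardized library,
# hit filtering by probability score, average-linkage diversity clustering of
# the hits on path-fingerprint Tanimoto distance, and cluster-representative
# selection.

#' Score a compound library with a trained model
#'
#' Standardizes the library with the same protocol as training, featurizes in
#' batches with the model's representation, and emits a probability score per
#' compound. Unparseable entries go to a reject log; they never abort the
#' run. Output order equals input order and is invariant to the batch size.
#'
#' @param model a `cs_model` from [fit_final()].
#' @param library_df data.frame with `compound_id`, `smiles`, and optionally
#'   `available` (logical, default `TRUE`).
#' @param scaler the training-split [fit_minmax()] scaler (required for
#'   descriptor-containing representations).
#' @param batch_size compounds per scoring batch.
#' @return list with `scored` (data.frame `compound_id`, `std_key`,
#'   `parent_smiles`, `ps`, `available`) and `rejects`.
#' @export
score_library <- function(model, library_df, scaler = NULL, batch_size = 1000L) {
  stopifnot(inherits(model, "cs_model"), batch_size >= 1L)
  std <- standardize_compounds(library_df[, c("compound_id", "smiles")])
  avail <- if ("available" %in% names(library_df)) {
    av <- library_df$available
    names(av) <- as.character(library_df$compound_id)
    av
  } else NULL
  dat <- std$std
  ps <- numeric(nrow(dat))
  kind <- model$spec$representation
  for (start in seq(1L, max(nrow(dat), 1L), by = batch_size)) {
    if (start > nrow(dat)) break
    idx <- start:min(start + batch_size - 1L, nrow(dat))
    X <- featurize(dat$std_key[idx], kind, scaler = scaler)
    ps[idx] <- predict_ps(model, X)
  }
  scored <- data.frame(compound_id = dat$compound_id,
                       std_key = dat$std_key,
                       parent_smiles = dat$parent_smiles,
                       ps = ps,
                       available = if (is.null(avail)) TRUE
                                   else as.logical(avail[dat$compound_id]),
                       stringsAsFactors = FALSE)
  list(scored = scored, rejects = std$rejects)
}

#' Featurize standardized SMILES under a representation kind
#'
#' @param smiles standardized SMILES vector.
#' @param kind a representation name from [feature_lengths()].
#' @param scaler training-split scaler, required when `kind` includes
#'   descriptors.
#' @return feature matrix of the declared length.
#' @export
featurize <- function(smiles, kind, scaler = NULL) {
  kind <- match.arg(kind, names(feature_lengths()))
  need_desc <- kind %in% c("descriptors", "hybridRR", "hybridMR", "hybridPR")
  if (need_desc && is.null(scaler))
    stop("representation '", kind, "' needs the training min-max scaler")
  desc <- if (need_desc) apply_minmax(scaler, calc_descriptors(smiles))
  switch(kind,
         path_fp = path_fp(smiles),
         morgan_fp = morgan_fp(smiles),
         dict_fp = dict_fp(smiles),
         descriptors = desc,
         hybridRR = hybrid_features(path_fp(smiles), desc),
         hybridMR = hybrid_features(morgan_fp(smiles), desc),
         hybridPR = hybrid_features(dict_fp(smiles), desc))
}

#' Filter screening hits by probability score
#'
#' Retains compounds with `ps >= ps_min` (inclusive, the hit-selection
#' convention; model-evaluation thresholds use strict `>`), sorted by ps
#' descending.
#'
#' @param scored the `scored` data.frame from [score_library()].
#' @param ps_min minimum probability score.
#' @param inclusive use `>=` (default) or strict `>`.
#' @return the filtered, sorted data.frame.
#' @export
filter_hits <- function(scored, ps_min = 0.8, inclusive = TRUE) {
  keep <- if (inclusive) scored$ps >= ps_min else scored$ps > ps_min
  hits <- scored[keep, , drop = FALSE]
  hits <- hits[order(-hits$ps, hits$compound_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Diversity clustering of screening hits
#'
#' Hierarchical agglomerative clustering under average linkage on the
#' distance `1 - Tanimoto` between path fingerprints, cut at the given
#' distance so that every merge inside a cluster happened at distance
#' `<= cut`.
#'
#' @param hits data.frame with `compound_id` and `std_key` (>= 1 row).
#' @param cut dendrogram cut distance.
#' @param fp optional precomputed path-fingerprint matrix for the hits.
#' @return list with `assignment` (data.frame `compound_id`, `cluster`),
#'   `n_clusters`, and the `hclust` tree (`NULL` for a single hit).
#' @export
cluster_hits <- function(hits, cut = 0.30, fp = NULL) {
  stopifnot(nrow(hits) >= 1L)
  if (nrow(hits) == 1L)
    return(list(assignment = data.frame(compound_id = hits$compound_id,
                                        cluster = 1L),
                n_clusters = 1L, tree = NULL))
  if (is.null(fp)) fp <- path_fp(hits$std_key)
  D <- 1 - tanimoto_kernel_matrix(fp)
  tree <- stats::hclust(stats::as.dist(D), method = "average")
  cl <- stats::cutree(tree, h = cut)
  list(assignment = data.frame(compound_id = hits$compound_id,
                               cluster = as.integer(cl)),
       n_clusters = length(unique(cl)), tree = tree)
}

#' Select one representative per cluster
#'
#' Within each cluster the available member with maximal probability score is
#' selected (ties broken by lexicographic compound id). Clusters with no
#' available member yield no representative and are reported in
#' `skipped_clusters`.
#'
#' @param assignment the `assignment` data.frame from [cluster_hits()].
#' @param hits the hits data.frame (with `ps` and `available`).
#' @return list with `representatives` (data.frame `compound_id`, `cluster`,
#'   `cluster_size`, `ps`, ordered by ps descending) and `skipped_clusters`.
#' @export
select_representatives <- function(assignment, hits) {
  if (nrow(assignment) == 0L)
    return(list(representatives = data.frame(), skipped_clusters = integer(0)))
  df <- merge(assignment, hits, by = "compound_id")
  reps <- list(); skipped <- integer(0)
  for (cl in sort(unique(df$cluster))) {
    mem <- df[df$cluster == cl, , drop = FALSE]
    av <- mem[mem$available, , drop = FALSE]
    if (nrow(av) == 0L) {
      message("cluster ", cl, ": no commercially available member; skipped")
      skipped <- c(skipped, cl)
      next
    }
    best <- av[order(-av$ps, av$compound_id)[1L], , drop = FALSE]
    reps[[length(reps) + 1L]] <- data.frame(
      compound_id = best$compound_id, cluster = cl,
      cluster_size = nrow(mem), ps = best$ps, stringsAsFactors = FALSE)
  }
  representatives <- if (length(reps)) do.call(rbind, reps) else data.frame()
  if (nrow(representatives))
    representatives <- representatives[order(-representatives$ps,
                                             representatives$compound_id), ,
                                       drop = FALSE]
  rownames(representatives) <- NULL
  list(representatives = representatives, skipped_clusters = skipped)
}
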