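# Bioactivity curation funnel: exact-record filtering, train/test partition by
# activity type, deduplication, active/inactive labeling with an exclusion
# window, censored-record augmentation of the inactive class, and decoy
# balancing, with conservation accounting at every stage.

.cs_unit_to_molar <- c(nM = 1e-9, uM = 1e-6, "µM" = 1e-6, M = 1)
.cs_activity_types <- c("IC50", "EC50", "Ki", "Kd")

#' Classification scheme parameters
#'
#' The lead-oriented (LO) scheme labels compounds with pActivity >= 6 (activity
#' <= 1 uM) active and pActivity <= 5.30 (>= 5 uM) inactive; the
#' potency-oriented (PO) scheme uses pActivity >= 7.5 (<= 31.6 nM) and
#' <= 5.5 (>= 3.2 uM). Compounds falling inside the exclusion window between
#' the thresholds are dropped. Both boundaries are inclusive.
#'
#' @param name `"LO"` or `"PO"`.
#' @return a `cs_scheme` list with `name`, `active_min_p`, `inactive_max_p`,
#'   and `inactive_cutoff_nM` (the concentration a censored ">" record must
#'   exceed, or reach, to certify inactivity).
#' @export
scheme_params <- function(name = c("LO", "PO")) {
  name <- match.arg(name)
  p <- if (name == "LO") c(active_min_p = 6.0, inactive_max_p = 5.30)
       else c(active_min_p = 7.5, inactive_max_p = 5.5)
  structure(list(name = name,
                 active_min_p = unname(p["active_min_p"]),
                 inactive_max_p = unname(p["inactive_max_p"]),
                 inactive_cutoff_nM = 10^(9 - unname(p["inactive_max_p"]))),
            class = "cs_scheme")
}

#' Parse and filter activity records
#'
#' Standardizes structures, converts reported concentrations to pActivity
#' (-log10 molar), and splits records into an exact pool (relation "=") and a
#' censored pool (relation ">"). Records with missing SMILES, unparseable
#' structures, unknown activity types, unknown units or non-positive values
#' are rejected with a reason code.
#'
#' @param records data.frame with columns `compound_id`, `smiles`,
#'   `activity_type`, `relation`, `value`, `units`.
#' @return list with data.frames `exact`, `censored` (columns `compound_id`,
#'   `std_key`, `parent_smiles`, `activity_type`, `value_nM`, `pActivity`;
#'   `pActivity` is `NA` for censored rows, which carry no exact claim) and
#'   `rejects` (`compound_id`, `reason`).
#' @export
filter_exact <- function(records) {
  req <- c("compound_id", "smiles", "activity_type", "relation", "value", "units")
  stopifnot(is.data.frame(records), all(req %in% names(records)))
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  reason[is.na(records$smiles) | !nzchar(trimws(records$smiles))] <- "missing_smiles"
  reason[is.na(reason) & !(records$activity_type %in% .cs_activity_types)] <-
    "unknown_activity_type"
  reason[is.na(reason) & !(records$relation %in% c("=", ">"))] <- "unknown_relation"
  reason[is.na(reason) & !(records$units %in% names(.cs_unit_to_molar))] <-
    "unknown_unit"
  val <- suppressWarnings(as.numeric(records$value))
  reason[is.na(reason) & (is.na(val) | val <= 0)] <- "missing_value"

  ok <- which(is.na(reason))
  std <- standardize_compounds(data.frame(
    compound_id = paste0("r", ok),
    smiles = records$smiles[ok], stringsAsFactors = FALSE))
  parsed <- as.integer(sub("^r", "", std$std$compound_id))
  failed <- setdiff(ok, parsed)
  reason[failed] <- "unparseable_smiles"

  molar <- val[parsed] * .cs_unit_to_molar[records$units[parsed]]
  pool <- data.frame(compound_id = as.character(records$compound_id[parsed]),
                     std_key = std$std$std_key,
                     parent_smiles = std$std$parent_smiles,
                     activity_type = records$activity_type[parsed],
                     relation = records$relation[parsed],
                     value_nM = molar * 1e9,
                     pActivity = -log10(molar),
                     stringsAsFactors = FALSE)
  pool$pActivity[pool$relation == ">"] <- NA_real_  # censored: bound only
  cols <- c("compound_id", "std_key", "parent_smiles", "activity_type",
            "value_nM", "pActivity")
  list(exact = pool[pool$relation == "=", cols],
       censored = pool[pool$relation == ">", cols],
       rejects = data.frame(compound_id = as.character(records$compound_id[!is.na(reason)]),
                            reason = reason[!is.na(reason)],
                            stringsAsFactors = FALSE))
}

#' Partition exact records into train and test pools by activity type
#'
#' IC50 records form the training pool; EC50/Ki/Kd records form the test pool.
#' For a compound measured both ways, only the IC50 rows survive (IC50 is
#' preferred to enrich the training set).
#'
#' @param exact the exact pool from [filter_exact()].
#' @return list with data.frames `train_pool`, `test_pool`.
#' @export
partition_by_type <- function(exact) {
  is_ic50 <- exact$activity_type == "IC50"
  train_keys <- unique(exact$std_key[is_ic50])
  list(train_pool = exact[is_ic50, , drop = FALSE],
       test_pool = exact[!is_ic50 & !(exact$std_key %in% train_keys), ,
                         drop = FALSE])
}

#' Collapse duplicate measurements
#'
#' One record per standardized structure: multiple exact values for the same
#' compound collapse to the median pActivity (order-independent and robust to
#' outliers).
#'
#' @param pool data.frame with `std_key` and `pActivity`.
#' @return data.frame with one row per `std_key`.
#' @export
deduplicate <- function(pool) {
  if (nrow(pool) == 0L) return(pool)
  med <- tapply(pool$pActivity, pool$std_key, stats::median)
  first <- pool[!duplicated(pool$std_key), , drop = FALSE]
  first$pActivity <- as.numeric(med[first$std_key])
  first$value_nM <- 10^(9 - first$pActivity)
  rownames(first) <- NULL
  first
}

#' Label compounds under a classification scheme
#'
#' pActivity at or above the active threshold gives the active label, at or
#' below the inactive threshold the inactive label; compounds inside the
#' exclusion window are dropped.
#'
#' @param pool deduplicated exact pool.
#' @param scheme a [scheme_params()].
#' @return data.frame `compound_id`, `std_key`, `parent_smiles`, `pActivity`,
#'   `label`, `source` (= "measured"); attribute `n_window` counts the
#'   window-excluded compounds.
#' @export
assign_labels <- function(pool, scheme) {
  stopifnot(inherits(scheme, "cs_scheme"))
  lab <- rep(NA_character_, nrow(pool))
  lab[pool$pActivity >= scheme$active_min_p] <- "active"
  lab[pool$pActivity <= scheme$inactive_max_p] <- "inactive"
  keep <- !is.na(lab)
  out <- data.frame(compound_id = pool$compound_id[keep],
                    std_key = pool$std_key[keep],
                    parent_smiles = pool$parent_smiles[keep],
                    pActivity = pool$pActivity[keep],
                    label = lab[keep], source = "measured",
                    stringsAsFactors = FALSE)
  attr(out, "n_window") <- sum(!keep)
  out
}

#' Recover inactives from censored ">" records
#'
#' A censored record certifies only a lower bound on the active concentration;
#' when that bound is at or beyond the scheme's inactivity cutoff the compound
#' is confidently inactive. Weaker bounds are discarded.
#'
#' @param censored the censored pool from [filter_exact()].
#' @param scheme a [scheme_params()].
#' @return data.frame like [assign_labels()] with `source = "censored_gt"`,
#'   attribute `n_discarded`.
#' @export
augment_censored_inactives <- function(censored, scheme) {
  stopifnot(inherits(scheme, "cs_scheme"))
  keep <- censored$value_nM >= scheme$inactive_cutoff_nM
  cen <- censored[keep, , drop = FALSE]
  cen <- cen[!duplicated(cen$std_key), , drop = FALSE]
  out <- data.frame(compound_id = cen$compound_id, std_key = cen$std_key,
                    parent_smiles = cen$parent_smiles,
                    pActivity = NA_real_, label = "inactive",
                    source = "censored_gt", stringsAsFactors = FALSE)
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Balance classes with decoys
#'
#' Samples exactly (actives - inactives) decoys uniformly without replacement
#' with a fixed seed, labels them inactive, and appends them.
#'
#' @param dataset labeled data.frame (columns as [assign_labels()]).
#' @param decoy_pool data.frame with `compound_id`, `std_key`, `parent_smiles`
#'   (or `smiles`).
#' @param seed integer seed.
#' @return the balanced data.frame.
#' @export
balance_with_decoys <- function(dataset, decoy_pool, seed = 1L) {
  n_act <- sum(dataset$label == "active")
  n_inact <- sum(dataset$label == "inactive")
  if (n_act < n_inact)
    stop("inactive class already exceeds active class; decoy balancing assumes ",
         "an active-skewed dataset")
  need <- n_act - n_inact
  if (need == 0L) return(dataset)
  if (nrow(decoy_pool) < need)
    stop("decoy pool too small: need ", need, ", have ", nrow(decoy_pool))
  pick <- .with_seed(seed, sample(nrow(decoy_pool), need))
  dec <- decoy_pool[pick, , drop = FALSE]
  if (!"parent_smiles" %in% names(dec)) dec$parent_smiles <- dec$smiles
  add <- data.frame(compound_id = dec$compound_id, std_key = dec$std_key,
                    parent_smiles = dec$parent_smiles, pActivity = NA_real_,
                    label = "inactive", source = "decoy",
                    stringsAsFactors = FALSE)
  out <- rbind(dataset, add)
  rownames(out) <- NULL
  out
}

#' Build balanced, disjoint train/test dataset pairs
#'
#' Runs the whole curation funnel for each classification scheme: exact
#' filtering, IC50-based train/test partition, deduplication, train-priority
#' overlap removal, labeling with the exclusion window, censored-inactive
#' augmentation, and decoy balancing with disjoint decoy draws for train and
#' test. Emits a funnel report whose stage counts are conserved.
#'
#' @param records raw activity data.frame (see [filter_exact()]).
#' @param decoys decoy data.frame with `compound_id`, `std_key`, `smiles`.
#' @param schemes list of [scheme_params()].
#' @param seed integer seed for decoy sampling.
#' @return list of `cs_dataset_pair` objects (fields `scheme`, `train`,
#'   `test`, `funnel`), named by scheme.
#' @export
build_datasets <- function(records, decoys,
                           schemes = list(scheme_params("LO"), scheme_params("PO")),
                           seed = 1L) {
  flt <- filter_exact(records)
  part <- partition_by_type(flt$exact)
  n_ic50 <- nrow(part$train_pool)
  n_non_ic50_kept <- nrow(part$test_pool)
  n_pref_dropped <- nrow(flt$exact) - n_ic50 - n_non_ic50_kept
  train_pool <- deduplicate(part$train_pool)
  test_pool0 <- deduplicate(part$test_pool)
  # train priority on collisions (partition_by_type already removes
  # cross-type collisions; this guards same-key collisions via salts etc.)
  n_overlap <- sum(test_pool0$std_key %in% train_pool$std_key)
  test_pool <- test_pool0[!(test_pool0$std_key %in% train_pool$std_key), ,
                          drop = FALSE]
  # censored rows follow the same partition rule: IC50 -> train side
  cen <- flt$censored[!duplicated(flt$censored$std_key), , drop = FALSE]
  cen_train <- cen[cen$activity_type == "IC50", , drop = FALSE]
  cen_test <- cen[cen$activity_type != "IC50" &
                    !(cen$std_key %in% cen_train$std_key), , drop = FALSE]

  out <- list()
  for (scheme in schemes) {
    stopifnot(inherits(scheme, "cs_scheme"))
    tr <- assign_labels(train_pool, scheme)
    ctr <- augment_censored_inactives(
      cen_train[!(cen_train$std_key %in% tr$std_key), , drop = FALSE], scheme)
    train <- rbind(tr, ctr)
    te <- assign_labels(test_pool, scheme)
    te_window <- attr(te, "n_window")
    n_te_cens_overlap <- sum(te$std_key %in% train$std_key)
    te <- te[!(te$std_key %in% train$std_key), , drop = FALSE]
    cte <- augment_censored_inactives(
      cen_test[!(cen_test$std_key %in% c(train$std_key, te$std_key)), ,
               drop = FALSE], scheme)
    test <- rbind(te, cte)

    pool <- decoys[!(decoys$std_key %in% c(train$std_key, test$std_key)), ,
                   drop = FALSE]
    need_tr <- sum(train$label == "active") - sum(train$label == "inactive")
    train <- balance_with_decoys(train, pool, seed = seed)
    pool <- pool[!(pool$std_key %in% train$std_key), , drop = FALSE]
    test <- balance_with_decoys(test, pool, seed = seed + 1L)

    for (side in list(train, test)) {
      if (!any(side$label == "active") || !any(side$label == "inactive"))
        stop("scheme ", scheme$name, ": a class is empty after labeling")
    }
    funnel <- list(
      input_records = nrow(records),
      rejected = nrow(flt$rejects),
      exact_records = nrow(flt$exact),
      censored_records = nrow(flt$censored),
      ic50_rows = n_ic50,
      non_ic50_rows_kept = n_non_ic50_kept,
      non_ic50_rows_dropped_pref = n_pref_dropped,
      train_dups_collapsed = n_ic50 - nrow(train_pool),
      test_dups_collapsed = n_non_ic50_kept - nrow(test_pool0),
      train_pool = nrow(train_pool),
      test_pool_initial = nrow(test_pool0),
      test_train_overlap_removed = n_overlap,
      test_pool = nrow(test_pool),
      train_measured = nrow(tr), test_measured = nrow(te),
      train_window_excluded = attr(tr, "n_window"),
      test_window_excluded = te_window,
      test_censored_overlap_removed = n_te_cens_overlap,
      train_censored_used = nrow(ctr), test_censored_used = nrow(cte),
      censored_discarded = attr(ctr, "n_discarded") + attr(cte, "n_discarded"),
      train_decoys = sum(train$source == "decoy"),
      test_decoys = sum(test$source == "decoy"),
      train_total = nrow(train), test_total = nrow(test))
    pair <- structure(list(scheme = scheme, train = train, test = test,
                           funnel = funnel), class = "cs_dataset_pair")
    validate_dataset_pair(pair)
    out[[scheme$name]] <- pair
  }
  out
}

#' Validate the invariants of a dataset pair
#'
#' Checks train/test disjointness by standardization key and exact class
#' balance on both sides.
#'
#' @param pair a `cs_dataset_pair`.
#' @return `pair`, invisibly; errors if an invariant fails.
#' @export
validate_dataset_pair <- function(pair) {
  stopifnot(inherits(pair, "cs_dataset_pair"))
  if (length(intersect(pair$train$std_key, pair$test$std_key)) > 0L)
    stop("train/test overlap by std_key in scheme ", pair$scheme$name)
  for (nm in c("train", "test")) {
    tab <- table(pair[[nm]]$label)
    if (length(tab) != 2L || tab[["active"]] != tab[["inactive"]])
      stop("unbalanced ", nm, " set in scheme ", pair$scheme$name)
  }
  invisible(pair)
}

#' Write a dataset pair to per-scheme CSVs plus a JSON funnel report
#'
#' @param pair a `cs_dataset_pair`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_dataset_pair <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, tolower(pair$scheme$name))
  cols <- c("std_key", "parent_smiles", "label", "source")
  utils::write.csv(pair$train[, cols], paste0(base, "_train.csv"),
                   row.names = FALSE)
  utils::write.csv(pair$test[, cols], paste0(base, "_test.csv"),
                   row.names = FALSE)
  writeLines(jsonlite::toJSON(pair$funnel, auto_unbox = TRUE, pretty = TRUE),
             paste0(base, "_funnel.json"))
  invisible(dir)
}
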