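rec <- function(id, smi, type = "IC50", rel = "=", value = 500, units = "nM") {
  data.frame(compound_id = id, smiles = smi, activity_type = type,
             relation = rel, value = value, units = units,
             stringsAsFactors = FALSE)
}

test_that("exact filtering routes censored rows aside and rejects malformed records", {
  records <- rbind(
    rec("a", "CCO", rel = ">", value = 10, units = "uM"),
    rec("b", "CCN", value = 500),
    rec("c", NA),
    rec("d", "CCC", units = "parsec"),
    rec("e", "CCCC", type = "XX50"),
    rec("f", "c1ccccc1C", type = "Ki", value = 2, units = "uM"))
  flt <- filter_exact(records)
  expect_equal(flt$censored$compound_id, "a")
  expect_setequal(flt$exact$compound_id, c("b", "f"))
  expect_setequal(flt$rejects$compound_id, c("c", "d", "e"))
  expect_equal(flt$rejects$reason[flt$rejects$compound_id == "d"], "unknown_unit")
  expect_equal(flt$rejects$reason[flt$rejects$compound_id == "c"], "missing_smiles")
  # pActivity invariant: -log10 of the molar value, within 1e-9
  b <- flt$exact[flt$exact$compound_id == "b", ]
  expect_equal(b$pActivity, -log10(500e-9), tolerance = 1e-9)
  # censored rows carry no exact pActivity claim
  expect_true(all(is.na(flt$censored$pActivity)))
})

test_that("IC50 records are preferred for training and remove the compound from the test pool", {
  records <- rbind(
    rec("t1", "CCO", type = "IC50", value = 100),
    rec("t1b", "OCC", type = "Ki", value = 80),   # same structure, Ki
    rec("t2", "CCN", type = "Kd", value = 50))
  flt <- filter_exact(records)
  part <- partition_by_type(flt$exact)
  expect_equal(part$train_pool$compound_id, "t1")
  expect_equal(part$test_pool$compound_id, "t2")  # Ki copy of t1 dropped
})

test_that("duplicate measurements collapse to the median pActivity", {
  records <- rbind(
    rec("d1", "CCO", value = 1000),   # pActivity 6
    rec("d2", "OCC", value = 100),    # same compound, pActivity 7
    rec("d3", "CCN", value = 10))
  flt <- filter_exact(records)
  dd <- deduplicate(flt$exact)
  expect_equal(nrow(dd), 2L)
  key <- make_std_key("CCO")
  expect_equal(dd$pActivity[dd$std_key == key], 6.5, tolerance = 1e-9)
  # distinct compounds unchanged
  expect_equal(nrow(deduplicate(flt$exact[3, ])), 1L)
})

test_that("scheme labeling applies inclusive thresholds and the exclusion window", {
  lo <- scheme_params("LO"); po <- scheme_params("PO")
  expect_equal(c(lo$active_min_p, lo$inactive_max_p), c(6.0, 5.30))
  expect_equal(c(po$active_min_p, po$inactive_max_p), c(7.5, 5.5))
  pool <- data.frame(compound_id = c("x", "y", "z"),
                     std_key = c("k1", "k2", "k3"),
                     parent_smiles = c("s", "s", "s"),
                     activity_type = "IC50", value_nM = 1,
                     pActivity = c(6.2, 5.7, 5.5))
  lab_lo <- assign_labels(pool, lo)
  expect_equal(lab_lo$label[lab_lo$compound_id == "x"], "active")
  expect_false("y" %in% lab_lo$compound_id)     # inside the 5.30-6 window
  expect_equal(attr(lab_lo, "n_window"), 2L)    # 5.7 and 5.5 both fall inside
  lab_po <- assign_labels(pool, po)
  expect_equal(lab_po$label[lab_po$compound_id == "z"], "inactive")  # boundary
})

test_that("censored records certify inactivity only beyond the scheme cutoff", {
  cen <- data.frame(compound_id = c("a", "b", "c"),
                    std_key = c("k1", "k2", "k3"), parent_smiles = "s",
                    activity_type = "IC50",
                    value_nM = c(10000, 2000, 3200), pActivity = NA_real_)
  lo <- augment_censored_inactives(cen, scheme_params("LO"))
  expect_setequal(lo$compound_id, "a")          # > 10 uM certifies, > 2 uM does not
  expect_equal(attr(lo, "n_discarded"), 2L)
  po <- augment_censored_inactives(cen, scheme_params("PO"))
  expect_setequal(po$compound_id, c("a", "c"))  # 3.2 uM boundary is inclusive
  expect_true(all(lo$label == "inactive") && all(lo$source == "censored_gt"))
})

test_that("decoy balancing equalizes classes with a seeded uniform draw", {
  ds <- data.frame(compound_id = paste0("m", 1:160),
                   std_key = paste0("k", 1:160), parent_smiles = "s",
                   pActivity = NA_real_,
                   label = c(rep("active", 100), rep("inactive", 60)),
                   source = "measured", stringsAsFactors = FALSE)
  pool <- data.frame(compound_id = paste0("d", 1:500),
                     std_key = paste0("dk", 1:500), smiles = "s",
                     stringsAsFactors = FALSE)
  bal <- balance_with_decoys(ds, pool, seed = 7L)
  expect_equal(sum(bal$source == "decoy"), 40L)
  expect_equal(sum(bal$label == "active"), sum(bal$label == "inactive"))
  expect_identical(balance_with_decoys(ds, pool, seed = 7L)$compound_id,
                   bal$compound_id)                    # seeded determinism
  expect_identical(balance_with_decoys(bal, pool[1:5, ], seed = 1L), bal)  # already balanced
  expect_error(balance_with_decoys(ds, pool[1:10, ], seed = 1L), "too small")
})

test_that("the full funnel yields balanced, disjoint dataset pairs with conserved counts", {
  act <- fx_activity()
  pairs <- build_datasets(act, fx_decoys(), seed = 5L)
  expect_named(pairs, c("LO", "PO"))
  for (pair in pairs) {
    expect_silent(validate_dataset_pair(pair))
    f <- pair$funnel
    # conservation identities, stage by stage
    expect_equal(f$input_records, f$rejected + f$exact_records + f$censored_records)
    expect_equal(f$exact_records,
                 f$ic50_rows + f$non_ic50_rows_kept + f$non_ic50_rows_dropped_pref)
    expect_equal(f$ic50_rows, f$train_pool + f$train_dups_collapsed)
    expect_equal(f$non_ic50_rows_kept, f$test_pool_initial + f$test_dups_collapsed)
    expect_equal(f$test_pool_initial, f$test_pool + f$test_train_overlap_removed)
    expect_equal(f$train_pool, f$train_measured + f$train_window_excluded)
    expect_equal(f$test_pool, f$test_measured + f$test_window_excluded +
                   f$test_censored_overlap_removed)
    expect_equal(f$train_total,
                 f$train_measured + f$train_censored_used + f$train_decoys)
    expect_equal(f$test_total,
                 f$test_measured + f$test_censored_used + f$test_decoys)
    # label re-derivability for measured compounds
    meas <- pair$train[pair$train$source == "measured", ]
    redrv <- ifelse(meas$pActivity >= pair$scheme$active_min_p, "active",
                    ifelse(meas$pActivity <= pair$scheme$inactive_max_p,
                           "inactive", NA))
    expect_identical(meas$label, redrv)
    # censored and decoy sources are always inactive
    expect_true(all(pair$train$label[pair$train$source != "measured"] == "inactive"))
  }
})

test_that("planted cross-pool duplicates never leak between train and test", {
  act <- fx_activity()
  # force collisions: re-emit 10 training (IC50) compounds as Ki test records
  ic50 <- act[act$activity_type == "IC50" & act$relation == "=", ][1:10, ]
  ic50$activity_type <- "Ki"
  ic50$compound_id <- paste0(ic50$compound_id, "_dup")
  pairs <- build_datasets(rbind(act, ic50), fx_decoys(), seed = 5L)
  for (pair in pairs)
    expect_length(intersect(pair$train$std_key, pair$test$std_key), 0L)
})
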