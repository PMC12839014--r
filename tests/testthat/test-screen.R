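fx_screen_model <- function() {
  if (is.null(.fx$screen_model)) {
    sep <- fx_sep()
    spec <- model_spec("RF", "path_fp", list(trees = 100L, mtry_rule = "sqrt"),
                       seed = 5L)
    .fx$screen_model <- fit_final(spec, sep$X, sep$y)
  }
  .fx$screen_model
}

test_that("library scoring is deterministic, batch-invariant, and logs rejects without aborting", {
  lib <- fx_library()
  model <- fx_screen_model()
  df <- data.frame(compound_id = lib$compound_id[1:40], smiles = lib$smiles[1:40])
  df$smiles[7] <- "C1CC"  # unparseable entry
  s1 <- score_library(model, df, batch_size = 1000L)
  s2 <- score_library(model, df, batch_size = 1L)
  expect_identical(s1$scored, s2$scored)
  s3 <- score_library(model, df, batch_size = 7L)
  expect_identical(s1$scored$ps, s3$scored$ps)
  expect_equal(s1$rejects$compound_id, lib$compound_id[7])
  expect_equal(nrow(s1$scored), 39L)
  expect_equal(s1$scored$compound_id, df$compound_id[-7])  # input order kept
  expect_true(all(s1$scored$ps >= 0 & s1$scored$ps <= 1))
  # a training active of separable data scores above 0.5
  sep <- fx_sep()
  act_i <- which(sep$y == "active")[1]
  sact <- score_library(model, data.frame(compound_id = "act",
                                          smiles = lib$smiles[act_i]))
  expect_gt(sact$scored$ps, 0.5)
})

test_that("hit filtering is inclusive at the threshold and monotone in ps_min", {
  scored <- data.frame(compound_id = paste0("m", 1:5),
                       std_key = paste0("k", 1:5), parent_smiles = "s",
                       ps = c(0.95, 0.8, 0.79, 0.5, 0.2), available = TRUE)
  h <- filter_hits(scored, 0.8)
  expect_equal(h$compound_id, c("m1", "m2"))   # 0.8 retained (>=), sorted desc
  expect_equal(nrow(filter_hits(scored, 0)), 5L)
  expect_lte(nrow(filter_hits(scored, 0.9)), nrow(filter_hits(scored, 0.8)))
  expect_equal(nrow(filter_hits(scored, 0.8, inclusive = FALSE)), 1L)
})

test_that("average-linkage clustering reproduces the three-point worked example", {
  # fingerprints engineered for d(A,B) = 0.1, d(A,C) = 0.9, d(B,C) ~ 0.84
  A <- c(rep(1, 18), rep(0, 22))
  B <- c(rep(1, 20), rep(0, 20))          # T(A,B) = 18/20 = 0.9
  C <- c(rep(0, 36), 1, 1, 1, 1)          # T(A,C) = 0, T(B,C) = 0
  C[1] <- 1                               # tiny overlap so distances differ
  fp <- rbind(A, B, C)
  hits <- data.frame(compound_id = c("A", "B", "C"), std_key = c("a", "b", "c"))
  cl <- cluster_hits(hits, cut = 0.30, fp = fp)
  expect_equal(cl$n_clusters, 2L)
  expect_equal(cl$assignment$cluster[1], cl$assignment$cluster[2])
  expect_false(cl$assignment$cluster[1] == cl$assignment$cluster[3])
  # the {A,B}-C average-linkage distance exceeds the cut
  D <- 1 - tanimoto_kernel_matrix(fp)
  expect_gt(mean(D[3, 1:2]), 0.30)
  # two identical compounds always share a cluster
  cl2 <- cluster_hits(data.frame(compound_id = c("x", "y"),
                                 std_key = c("k", "k")),
                      cut = 0.30, fp = rbind(A, A))
  expect_equal(cl2$n_clusters, 1L)
})

test_that("clustering equals an exhaustive average-linkage oracle on small instances", {
  set.seed(31)
  tried <- 0L
  for (i in 1:40) {
    n <- sample(3:8, 1)
    fp <- matrix(rbinom(n * 128, 1, 0.35), n)
    D <- 1 - tanimoto_kernel_matrix(fp)
    off <- D[upper.tri(D)]
    if (anyDuplicated(signif(off, 9))) next  # tie conventions may differ
    tried <- tried + 1L
    cut <- stats::quantile(off, runif(1, 0.2, 0.8))
    hits <- data.frame(compound_id = paste0("m", 1:n),
                       std_key = paste0("k", 1:n))
    got <- cluster_hits(hits, cut = cut, fp = fp)$assignment$cluster
    want <- oracle_avg_cluster(D, cut)
    expect_true(same_partition(got, want),
                label = paste("instance", i, "n =", n))
  }
  expect_gt(tried, 20L)
})

test_that("the number of clusters is non-increasing in the cut distance", {
  set.seed(17)
  fp <- matrix(rbinom(15 * 64, 1, 0.3), 15)
  hits <- data.frame(compound_id = paste0("m", 1:15), std_key = paste0("k", 1:15))
  sizes <- vapply(c(0.1, 0.2, 0.3, 0.5, 0.7, 0.9),
                  function(ct) cluster_hits(hits, cut = ct, fp = fp)$n_clusters, 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("representative selection honours availability, PS and id tie-breaks", {
  hits <- data.frame(compound_id = c("u", "v", "w", "x", "y"),
                     std_key = paste0("k", 1:5), parent_smiles = "s",
                     ps = c(0.95, 0.91, 0.9, 0.9, 0.85),
                     available = c(FALSE, TRUE, TRUE, TRUE, FALSE))
  asg <- data.frame(compound_id = c("u", "v", "w", "x", "y"),
                    cluster = c(1L, 1L, 2L, 2L, 3L))
  res <- suppressMessages(select_representatives(asg, hits))
  reps <- res$representatives
  expect_equal(reps$compound_id[reps$cluster == 1], "v")  # best available, not 0.95
  expect_equal(reps$compound_id[reps$cluster == 2], "w")  # ps tie -> lexicographic
  expect_equal(res$skipped_clusters, 3L)                  # no available member
  expect_equal(reps$cluster_size[reps$cluster == 1], 2L)
  # all-available cluster: plain argmax
  hits$available <- TRUE
  res2 <- select_representatives(asg, hits)
  expect_equal(res2$representatives$compound_id[res2$representatives$cluster == 1], "u")
  expect_length(res2$skipped_clusters, 0L)
  # degenerate input
  empty <- select_representatives(data.frame(compound_id = character(0),
                                             cluster = integer(0)), hits)
  expect_equal(nrow(empty$representatives), 0L)
})
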