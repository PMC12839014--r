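test_that("the declared grids have the exact cardinalities of the model zoo", {
  g <- grid_definition()
  expect_equal(vapply(g, nrow, 0L),
               c(RF = 6L, SVM = 5L, KNN = 14L, GP = 5L, MLP = 12L))
  expect_equal(sort(unique(g$KNN$k)), seq(3L, 15L, 2L))
  expect_setequal(g$SVM$kernel, c("linear", "poly", "rbf", "sigmoid", "tanimoto"))
  expect_setequal(g$GP$kernel, c("dotproduct", "rationalquadratic", "matern",
                                 "whitenoise", "rbf"))
  expect_setequal(unique(g$MLP$width), c(100L, 200L, 1000L))
})

test_that("the tanimoto kernel matrix matches the binary tanimoto and is PSD", {
  set.seed(3)
  X <- matrix(rbinom(20 * 64, 1, 0.2), 20)
  K <- tanimoto_kernel_matrix(X)
  for (i in 1:5) for (j in 1:5)
    expect_equal(K[i, j], tanimoto(X[i, ], X[j, ]), tolerance = 1e-12)
  expect_equal(unname(diag(K)), rep(1, 20))
  expect_identical(K, t(K))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  # zero rows give 0 by convention
  X0 <- rbind(X[1, ], 0)
  expect_equal(tanimoto_kernel_matrix(X0)[1, 2], 0)
})

test_that("vectorized kernel classes agree with their element-wise definitions", {
  set.seed(4)
  X <- matrix(rnorm(8 * 10), 8)
  B <- matrix(rbinom(8 * 10, 1, 0.4), 8)
  for (kern in list(tanimoto_kernel(), matern_kernel(2), rq_kernel(1.5, 2),
                    whitenoise_kernel())) {
    M <- if (is(kern, "cs_tanikernel")) B else X
    K <- kernlab::kernelMatrix(kern, M)
    for (i in 1:4) for (j in 1:4)
      expect_equal(K[i, j], kern(M[i, ], M[j, ]), tolerance = 1e-10)
  }
})

test_that("every algorithm emits deterministic probability scores in [0, 1]", {
  sep <- fx_sep()
  red <- reduced_grids()
  n <- nrow(sep$X)
  idx <- seq_len(n) %% 4 != 0
  for (alg in c("RF", "SVM", "KNN", "GP", "MLP")) {
    spec <- model_spec(alg, "path_fp", as.list(red[[alg]][1, , drop = FALSE]),
                       seed = 11L)
    m <- fit_model(spec, sep$X[idx, ], sep$y[idx])
    ps1 <- predict_ps(m, sep$X[!idx, ])
    ps2 <- predict_ps(m, sep$X[!idx, ])
    expect_identical(ps1, ps2)
    expect_true(all(ps1 >= 0 & ps1 <= 1))
    # planted-signal data is nearly separable: training actives score high
    tr_act <- predict_ps(m, sep$X[idx & sep$y == "active", ])
    expect_gt(mean(tr_act > 0.5), 0.8)
  }
})

test_that("KNN probability scores follow the weighting conventions", {
  X <- rbind(c(0, 0), c(1, 0), c(4, 0), c(5, 0), c(6, 0))
  y <- c("active", "active", "inactive", "inactive", "inactive")
  m <- fit_model(model_spec("KNN", "path_fp", list(k = 3, weights = "uniform")),
                 X, y)
  expect_equal(predict_ps(m, rbind(c(0.4, 0))), 2 / 3)
  md <- fit_model(model_spec("KNN", "path_fp", list(k = 3, weights = "distance")),
                  X, y)
  # neighbours of (0.9, 0): A at 0.9, B at 0.1, C at 3.1; weights 1/d
  w <- 1 / c(0.9, 0.1, 3.1)
  expect_equal(predict_ps(md, rbind(c(0.9, 0))), sum(w[1:2]) / sum(w),
               tolerance = 1e-12)
  # a zero-distance neighbour takes all the weight
  expect_equal(predict_ps(md, rbind(c(4, 0))), 0)
})

test_that("stratified cross-validation is seeded, reproducible, and refuses degenerate folds", {
  sep <- fx_sep()
  spec <- model_spec("RF", "path_fp", list(trees = 100L, mtry_rule = "sqrt"),
                     seed = 3L)
  cv1 <- five_fold_cv(spec, sep$X, sep$y, seed = 21L)
  cv2 <- five_fold_cv(spec, sep$X, sep$y, seed = 21L)
  expect_identical(cv1$per_fold, cv2$per_fold)
  expect_length(cv1$per_fold, 5L)
  expect_gte(cv1$sd, 0)
  # separable planted structure: every fold classifies near-perfectly
  expect_true(all(cv1$per_fold >= 0.8))
  expect_error(five_fold_cv(spec, sep$X[1:6, ], rep("active", 6), seed = 1L),
               "single class|degenerate")
})

test_that("label-shuffled controls score near zero MCC", {
  sep <- fx_sep()
  spec <- model_spec("RF", "path_fp", list(trees = 100L, mtry_rule = "sqrt"),
                     seed = 3L)
  mccs <- vapply(1:5, function(s) {
    set.seed(s)
    ysh <- sample(sep$y)
    cv <- five_fold_cv(spec, sep$X, ysh, seed = s)
    cv$mean
  }, 0)
  expect_lt(abs(mean(mccs)), 3 * max(sd(mccs), 0.05))
})

test_that("grid search returns the argmax of cross-validated MCC with ordered tie-break", {
  sep <- fx_sep()
  one <- data.frame(trees = 100L, mtry_rule = "sqrt", stringsAsFactors = FALSE)
  gs1 <- grid_search("RF", "path_fp", sep$X, sep$y, seed = 2L, grid = one)
  expect_equal(gs1$best$hyperparams$trees, 100L)
  expect_equal(nrow(gs1$results), 1L)
  gs <- grid_search("RF", "path_fp", sep$X, sep$y, seed = 2L, k = 3L)
  expect_equal(nrow(gs$results), 6L)               # full RF enumeration
  best_mcc <- gs$results$cv_mcc[which.max(gs$results$cv_mcc)]
  expect_true(all(best_mcc >= gs$results$cv_mcc))  # argmax property
  # the returned spec reproduces the best row's score
  i <- which(gs$results$cv_mcc == best_mcc)[1]
  expect_identical(gs$best$hyperparams$mtry_rule, gs$results$mtry_rule[i])
})

test_that("the MLP learns a separable rule and respects architecture settings", {
  set.seed(9)
  X <- matrix(runif(400), 200)
  y <- ifelse(X[, 1] + X[, 2] > 1, "active", "inactive")
  fit <- chemsieve:::mlp_fit(X, as.integer(y == "active"), layers = 3L,
                             width = 16L, batch = 50L, seed = 1L, epochs = 200L)
  expect_length(fit$par$W, 4L)  # 3 hidden + output
  ps <- chemsieve:::mlp_predict(fit, X)
  expect_gt(mean((ps > 0.5) == (y == "active")), 0.9)
})
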