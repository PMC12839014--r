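# The five-algorithm model zoo: random forest, kernel SVM, k-nearest
# neighbours, Gaussian process and multi-layer perceptron, each with the
# declared hyperparameter grid, exhaustive grid search maximizing MCC under
# stratified cross-validation, and probability-score prediction.

.cs_algorithms <- c("RF", "SVM", "KNN", "GP", "MLP")

#' Hyperparameter grids of the model zoo
#'
#' One data.frame of grid points per algorithm, in a fixed order of
#' increasing model complexity (the grid-search tie-break): RF has 6 points
#' (trees x features-per-split rule), SVM 5 (kernel), KNN 14 (k x weighting),
#' GP 5 (kernel), MLP 12 (layers x width x batch).
#'
#' @return named list of data.frames.
#' @export
grid_definition <- function() {
  list(
    RF = expand.grid(mtry_rule = c("all", "sqrt", "log2"),
                     trees = c(100L, 500L),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, 2:1],
    SVM = data.frame(kernel = c("linear", "poly", "rbf", "sigmoid", "tanimoto"),
                     stringsAsFactors = FALSE),
    KNN = expand.grid(weights = c("uniform", "distance"),
                      k = seq(3L, 15L, by = 2L),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, 2:1],
    GP = data.frame(kernel = c("dotproduct", "rationalquadratic", "matern",
                               "whitenoise", "rbf"),
                    stringsAsFactors = FALSE),
    MLP = expand.grid(batch = c(100L, 200L),
                      width = c(100L, 200L, 1000L),
                      layers = c(2L, 3L),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, 3:1]
  )
}

#' Define a model configuration
#'
#' @param algorithm one of RF, SVM, KNN, GP, MLP.
#' @param representation a feature kind name (see [feature_lengths()]).
#' @param hyperparams named list: one row of the algorithm's grid.
#' @param seed integer seed used for every stochastic component of the fit.
#' @return a `cs_model_spec`.
#' @export
model_spec <- function(algorithm, representation, hyperparams, seed = 1L) {
  algorithm <- match.arg(algorithm, .cs_algorithms)
  stopifnot(representation %in% names(feature_lengths()))
  structure(list(algorithm = algorithm, representation = representation,
                 hyperparams = as.list(hyperparams), seed = as.integer(seed)),
            class = "cs_model_spec")
}

.cs_yfac <- function(y) {
  stopifnot(all(y %in% c("active", "inactive")))
  factor(y, levels = c("inactive", "active"))
}

.cs_gamma_scale <- function(X) {
  v <- stats::var(as.vector(X))
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(X) * v)
}

.cs_svm_kernel <- function(name, X) {
  sc <- .cs_gamma_scale(X)
  switch(name,
         linear = kernlab::vanilladot(),
         poly = kernlab::polydot(degree = 3, scale = sc, offset = 0),
         rbf = kernlab::rbfdot(sigma = sc),
         sigmoid = kernlab::tanhdot(scale = sc, offset = 0),
         tanimoto = tanimoto_kernel(),
         stop("unknown SVM kernel: ", name))
}

.cs_gp_kernel <- function(name, X) {
  l <- .cs_median_dist(X)
  switch(name,
         dotproduct = kernlab::vanilladot(),
         rbf = kernlab::rbfdot(sigma = 1 / (2 * l^2)),
         matern = matern_kernel(l = l),
         rationalquadratic = rq_kernel(l = l, alpha = 1),
         whitenoise = whitenoise_kernel(),
         stop("unknown GP kernel: ", name))
}

#' Fit one model configuration
#'
#' @param spec a [model_spec()].
#' @param X feature matrix (rows = compounds).
#' @param y labels, `"active"` / `"inactive"`.
#' @return a `cs_model` whose `predict_ps()` output is deterministic given
#'   the fitted state.
#' @export
fit_model <- function(spec, X, y) {
  stopifnot(inherits(spec, "cs_model_spec"), nrow(X) == length(y))
  X <- as.matrix(X)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  yf <- .cs_yfac(y)
  if (nlevels(droplevels(yf)) < 2L)
    stop("training data contains a single class")
  hp <- spec$hyperparams
  fit <- switch(spec$algorithm,
    RF = {
      mtry <- switch(hp$mtry_rule,
                     all = ncol(X),
                     sqrt = max(1L, floor(sqrt(ncol(X)))),
                     log2 = max(1L, floor(log2(ncol(X)))))
      ranger::ranger(x = X, y = yf, num.trees = hp$trees, mtry = mtry,
                     probability = TRUE, seed = spec$seed, num.threads = 1L)
    },
    SVM = {
      set.seed(spec$seed)
      k <- .cs_svm_kernel(hp$kernel, X)
      m <- tryCatch(
        kernlab::ksvm(X, yf, type = "C-svc", C = 1, kernel = k,
                      prob.model = TRUE, scaled = FALSE),
        error = function(e) NULL)
      if (is.null(m) || length(kernlab::prob.model(m)[[1]]) == 0) {
        # Platt scaling on training decision values when kernlab's internal
        # calibration fails (e.g. perfectly separable folds)
        m2 <- kernlab::ksvm(X, yf, type = "C-svc", C = 1, kernel = k,
                            prob.model = FALSE, scaled = FALSE)
        dv <- kernlab::predict(m2, X, type = "decision")[, 1]
        cal <- stats::glm((yf == "active") ~ dv, family = stats::binomial())
        list(svm = m2, platt = cal)
      } else m
    },
    KNN = list(X = X, y = yf, k = hp$k, weights = hp$weights),
    GP = {
      set.seed(spec$seed)
      k <- .cs_gp_kernel(hp$kernel, X)
      kernlab::gausspr(X, yf, kernel = k, scaled = FALSE)
    },
    MLP = mlp_fit(X, as.integer(yf == "active"), layers = hp$layers,
                  width = hp$width, batch = hp$batch, seed = spec$seed,
                  epochs = if (is.null(hp$epochs)) 40L else hp$epochs))
  structure(list(spec = spec, fit = fit, p = ncol(X),
                 train_hash = c(n = nrow(X), p = ncol(X), s = sum(X))),
            class = "cs_model")
}

.cs_knn_ps <- function(fit, X) {
  D2 <- .cs_sqdist(as.matrix(X), fit$X)
  act <- fit$y == "active"
  apply(D2, 1, function(d2) {
    o <- order(d2)[seq_len(fit$k)]
    if (fit$weights == "uniform") return(mean(act[o]))
    d <- sqrt(d2[o])
    if (any(d == 0)) return(mean(act[o][d == 0]))
    w <- 1 / d
    sum(w * act[o]) / sum(w)
  })
}

#' Probability-score prediction
#'
#' Emits the probability score PS in `[0, 1]` that each compound is an
#' active inhibitor; the predicted label is active iff PS > 0.5.
#'
#' @param model a `cs_model` from [fit_model()] / [fit_final()].
#' @param X feature matrix with the same representation as training.
#' @return numeric vector of PS values.
#' @export
predict_ps <- function(model, X) {
  stopifnot(inherits(model, "cs_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$p)
    stop("feature-kind mismatch: model was trained on ", model$p,
         " features, got ", ncol(X))
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  ps <- switch(model$spec$algorithm,
    RF = stats::predict(model$fit, data = X, num.threads = 1L)$predictions[, "active"],
    SVM = {
      if (is.list(model$fit) && !is.null(model$fit$platt)) {
        dv <- kernlab::predict(model$fit$svm, X, type = "decision")[, 1]
        as.numeric(stats::predict(model$fit$platt,
                                  newdata = data.frame(dv = dv),
                                  type = "response"))
      } else {
        kernlab::predict(model$fit, X, type = "probabilities")[, "active"]
      }
    },
    KNN = .cs_knn_ps(model$fit, X),
    GP = kernlab::predict(model$fit, X, type = "probabilities")[, "active"],
    MLP = mlp_predict(model$fit, X))
  ps <- as.numeric(ps)
  pmin(pmax(ps, 0), 1)
}

# stratified fold assignment: each fold holds ~1/k of every class
.cs_stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  set.seed(seed)
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Stratified 5-fold cross-validation of one configuration
#'
#' Each fold trains on 80% of the training set and validates on the held-out
#' 20%, stratified by class; reports the per-fold MCC with mean and standard
#' deviation. Seeded and reproducible.
#'
#' @inheritParams fit_model
#' @param seed fold-assignment seed.
#' @param k number of folds.
#' @return list with `per_fold`, `mean`, `sd`.
#' @export
five_fold_cv <- function(spec, X, y, seed = 1L, k = 5L) {
  X <- as.matrix(X)
  folds <- .cs_stratified_folds(y, k, seed)
  per_fold <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L)
      stop("degenerate fold (single class); dataset too small or unbalanced")
    m <- fit_model(spec, X[tr, , drop = FALSE], y[tr])
    ps <- predict_ps(m, X[!tr, , drop = FALSE])
    per_fold[f] <- mcc(confusion_at_threshold(ps, y[!tr], 0.5))
  }
  list(per_fold = per_fold, mean = mean(per_fold), sd = stats::sd(per_fold))
}

#' Exhaustive grid search maximizing cross-validated MCC
#'
#' Evaluates every grid point of the algorithm by stratified k-fold CV on the
#' training set only and returns the argmax of mean MCC. Exact ties resolve
#' to the earliest grid point, and the grids are declared in order of
#' increasing complexity, so ties prefer the simpler model.
#'
#' @param algorithm one of RF, SVM, KNN, GP, MLP.
#' @param representation feature kind (recorded in the specs).
#' @param X,y training split.
#' @param seed CV fold seed (also the fit seed for every point).
#' @param k folds.
#' @param grid optional subset of the algorithm's grid (data.frame); default
#'   the full declared grid.
#' @return list with `best` (a [model_spec()]), `results` (per-point mean/sd
#'   MCC), `algorithm`.
#' @export
grid_search <- function(algorithm, representation, X, y, seed = 1L, k = 5L,
                        grid = NULL) {
  algorithm <- match.arg(algorithm, .cs_algorithms)
  if (is.null(grid)) grid <- grid_definition()[[algorithm]]
  stopifnot(nrow(grid) >= 1L)
  res <- grid
  res$cv_mcc <- NA_real_
  res$cv_sd <- NA_real_
  for (i in seq_len(nrow(grid))) {
    spec <- model_spec(algorithm, representation,
                       as.list(grid[i, , drop = FALSE]), seed = seed)
    cv <- five_fold_cv(spec, X, y, seed = seed, k = k)
    res$cv_mcc[i] <- cv$mean
    res$cv_sd[i] <- cv$sd
  }
  best_i <- which.max(res$cv_mcc)  # first maximum = simplest on ties
  list(best = model_spec(algorithm, representation,
                         as.list(grid[best_i, , drop = FALSE]), seed = seed),
       results = res, algorithm = algorithm)
}

#' Retrain the selected configuration on the complete training set
#'
#' @inheritParams fit_model
#' @return a `cs_model`.
#' @export
fit_final <- function(spec, X, y) fit_model(spec, X, y)
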