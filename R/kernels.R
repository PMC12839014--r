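# Kernels for the SVM and Gaussian-process models. Each custom kernel is a
# proper kernlab S4 kernel class with vectorized kernelMatrix / kernelMult /
# kernelPol / kernelFast methods, so kernlab's solvers never fall back to
# element-wise R evaluation.

#' Tanimoto kernel matrix
#'
#' `K[i, j] = <x, y> / (<x, x> + <y, y> - <x, y>)`. On binary fingerprint
#' rows this equals the Tanimoto similarity; on continuous (hybrid) rows it
#' is the natural inner-product generalization. Zero rows give 0 by
#' convention.
#'
#' @param X,Y numeric matrices with matching column count (`Y = NULL` means
#'   `Y = X`).
#' @return numeric matrix `nrow(X)` by `nrow(Y)`.
#' @export
tanimoto_kernel_matrix <- function(X, Y = NULL) {
  if (is.null(Y)) Y <- X
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(ncol(X) == ncol(Y))
  XY <- tcrossprod(X, Y)
  den <- outer(rowSums(X^2), rowSums(Y^2), "+") - XY
  K <- XY / den
  K[den <= 0] <- 0
  K
}

.cs_sqdist <- function(X, Y) {
  D2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  D2[D2 < 0] <- 0
  D2
}

# median pairwise Euclidean distance on (a subsample of) the training rows;
# the length-scale default for the stationary GP kernels
.cs_median_dist <- function(X, max_n = 200L) {
  n <- nrow(X)
  idx <- if (n > max_n) round(seq(1, n, length.out = max_n)) else seq_len(n)
  d <- sqrt(.cs_sqdist(X[idx, , drop = FALSE], X[idx, , drop = FALSE]))
  d <- d[upper.tri(d)]
  d <- d[d > 0]
  if (!length(d)) return(1)
  stats::median(d)
}

#' @import methods
setClass("cs_tanikernel", contains = "kernel")
setClass("cs_matkernel", contains = "kernel", representation(l = "numeric"))
setClass("cs_rqkernel", contains = "kernel",
         representation(l = "numeric", alpha = "numeric"))
setClass("cs_whitekernel", contains = "kernel")

.cs_gram <- function(kernel, x, y) {
  if (is(kernel, "cs_tanikernel")) return(tanimoto_kernel_matrix(x, y))
  if (is(kernel, "cs_matkernel")) {
    d <- sqrt(.cs_sqdist(x, y)) / kernel@l
    return((1 + sqrt(3) * d) * exp(-sqrt(3) * d))  # Matern nu = 3/2
  }
  if (is(kernel, "cs_rqkernel"))
    return((1 + .cs_sqdist(x, y) / (2 * kernel@alpha * kernel@l^2))^(-kernel@alpha))
  if (is(kernel, "cs_whitekernel"))
    return((.cs_sqdist(x, y) < 1e-12) * 1)
  stop("unknown kernel class")
}

.cs_kernel_methods <- function(cls) {
  setMethod(kernlab::kernelMatrix, signature(kernel = cls, x = "matrix"),
    function(kernel, x, y = NULL) {
      if (is.null(y)) y <- x
      kernlab::as.kernelMatrix(.cs_gram(kernel, x, y))
    })
  setMethod(kernlab::kernelMult, signature(kernel = cls, x = "matrix"),
    function(kernel, x, y = NULL, z, blocksize = 256) {
      if (is.null(y)) y <- x
      .cs_gram(kernel, x, y) %*% z
    })
  setMethod(kernlab::kernelPol, signature(kernel = cls, x = "matrix"),
    function(kernel, x, y = NULL, z, k = NULL) {
      if (is.null(y)) y <- x
      if (is.null(k)) k <- z
      .cs_gram(kernel, x, y) * outer(as.vector(z), as.vector(k))
    })
  setMethod(kernlab::kernelFast, signature(kernel = cls, x = "matrix"),
    function(kernel, x, y, a) .cs_gram(kernel, x, y))
}
.cs_kernel_methods("cs_tanikernel")
.cs_kernel_methods("cs_matkernel")
.cs_kernel_methods("cs_rqkernel")
.cs_kernel_methods("cs_whitekernel")

#' Kernel constructors for the model zoo
#'
#' `tanimoto_kernel()` builds the Tanimoto kernel; `matern_kernel(l)` the
#' Matern (nu = 3/2) kernel; `rq_kernel(l, alpha)` the rational-quadratic
#' kernel; `whitenoise_kernel()` the white-noise (identity-on-duplicates)
#' kernel. All are kernlab-compatible kernel objects.
#'
#' @param l length scale (> 0).
#' @param alpha rational-quadratic shape parameter (> 0).
#' @return a kernlab kernel object.
#' @export
tanimoto_kernel <- function() {
  new("cs_tanikernel", .Data = function(x, y = NULL) {
    if (is.null(y)) y <- x
    as.numeric(tanimoto_kernel_matrix(rbind(x), rbind(y)))
  }, kpar = list())
}

#' @rdname tanimoto_kernel
#' @export
matern_kernel <- function(l = 1) {
  stopifnot(l > 0)
  new("cs_matkernel", .Data = function(x, y = NULL) {
    if (is.null(y)) y <- x
    d <- sqrt(sum((x - y)^2)) / l
    (1 + sqrt(3) * d) * exp(-sqrt(3) * d)
  }, kpar = list(l = l), l = l)
}

#' @rdname tanimoto_kernel
#' @export
rq_kernel <- function(l = 1, alpha = 1) {
  stopifnot(l > 0, alpha > 0)
  new("cs_rqkernel", .Data = function(x, y = NULL) {
    if (is.null(y)) y <- x
    (1 + sum((x - y)^2) / (2 * alpha * l^2))^(-alpha)
  }, kpar = list(l = l, alpha = alpha), l = l, alpha = alpha)
}

#' @rdname tanimoto_kernel
#' @export
whitenoise_kernel <- function() {
  new("cs_whitekernel", .Data = function(x, y = NULL) {
    if (is.null(y)) y <- x
    as.numeric(sum((x - y)^2) < 1e-12)
  }, kpar = list())
}
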