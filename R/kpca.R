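# Stage 3: kernel PCA of the filter-bank CSP vectors. With the Gaussian
# kernel this yields the nonlinear KEFB-CSP components; with a degree-1
# polynomial kernel it reduces exactly to ordinary PCA of the input.

#' Gaussian kernel between two vectors
#'
#' `exp(-||x - y||^2 / (2 sigma^2))`; in (0, 1], symmetric.
#'
#' @param x,y numeric vectors of equal length.
#' @param sigma kernel width, `> 0`.
#' @return scalar kernel value.
#' @export
gaussian_kernel <- function(x, y, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a positive scalar")
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  exp(-sum((x - y)^2) / (2 * sigma^2))
}

#' Polynomial kernel between two vectors
#'
#' `(x . y)^degree`; degree 1 is the plain inner product (linear kernel).
#'
#' @param x,y numeric vectors of equal length.
#' @param degree polynomial degree `c >= 1`.
#' @return scalar kernel value.
#' @export
polynomial_kernel <- function(x, y, degree = 1) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  sum(x * y)^degree
}

# Full kernel matrices, vectorized. X, Y: rows = observations.
.kernel_matrix <- function(X, Y = NULL, kernel = "gaussian", sigma = 1,
                           degree = 1) {
  if (is.null(Y)) Y <- X
  if (kernel == "gaussian") {
    d2 <- .sqdist(X, Y)
    exp(-d2 / (2 * sigma^2))
  } else {
    (X %*% t(Y))^degree
  }
}

.sqdist <- function(X, Y) {
  xx <- rowSums(X^2); yy <- rowSums(Y^2)
  d2 <- outer(xx, yy, "+") - 2 * X %*% t(Y)
  pmax(d2, 0)
}

#' Double-center a kernel matrix
#'
#' `Kc = K - 1n K - K 1n + 1n K 1n` with `1n` the n x n matrix of `1/n`,
#' i.e. the Gram matrix of the feature-space-centered data. Row and column
#' means of the result are zero.
#'
#' @param K symmetric n x n kernel matrix.
#' @return centered n x n matrix.
#' @export
center_kernel <- function(K) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("kernel matrix must be square")
  n <- nrow(K)
  cm <- colMeans(K)
  rm_ <- rowMeans(K)
  gm <- mean(K)
  K - matrix(cm, n, n, byrow = TRUE) - matrix(rm_, n, n) + gm
}

#' Fit kernel PCA on a set of feature vectors
#'
#' Eigendecomposes the centered kernel matrix of the training vectors and
#' retains the `d` largest positive eigenpairs. Expansion coefficients are
#' by default scaled by `1/sqrt(eigval)` so every feature-space projection
#' direction has unit norm; `paper_literal_scaling = TRUE` divides the unit
#' eigenvector by the eigenvalue itself instead (changing only per-component
#' scale, not direction).
#'
#' @param X n x q matrix of training vectors in rows.
#' @param sigma Gaussian kernel width (ignored for the polynomial kernel).
#' @param d number of components, `1 <= d <= n`; silently truncated (with a
#'   warning and `truncated` flag) if fewer positive eigenvalues exist.
#' @param kernel `"gaussian"` or `"polynomial"`.
#' @param poly_degree degree of the polynomial kernel; degree 1 makes the
#'   method identical to ordinary PCA.
#' @param paper_literal_scaling use `a/lambda` coefficient scaling instead
#'   of the unit-norm `a/sqrt(lambda)` convention.
#' @param literal_eq14 project test points with the uncentered kernel
#'   vector instead of centering it against training statistics.
#' @return an object of class `kpca_model`; training projections are in
#'   `$projections` (n x d).
#' @export
fit_kpca <- function(X, sigma = 1, d = 2L, kernel = c("gaussian", "polynomial"),
                     poly_degree = 1, paper_literal_scaling = FALSE,
                     literal_eq14 = FALSE) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  n <- nrow(X)
  d <- as.integer(d)
  if (d < 1L || d > n) stop(sprintf("'d' must be in 1..%d", n))
  if (kernel == "gaussian" && (!is.numeric(sigma) || sigma <= 0))
    stop("'sigma' must be a positive scalar")
  K <- .kernel_matrix(X, kernel = kernel, sigma = sigma, degree = poly_degree)
  Kc <- center_kernel(K)
  Kc <- (Kc + t(Kc)) / 2
  eg <- eigen(Kc, symmetric = TRUE)
  tol <- 1e-10 * max(abs(eg$values), 1e-300)
  pos <- which(eg$values > tol)
  truncated <- FALSE
  if (length(pos) < d) {
    warning(sprintf("only %d positive eigenvalues available; d truncated from %d",
                    length(pos), d))
    d <- length(pos)
    truncated <- TRUE
  }
  if (d < 1L) stop("centered kernel matrix has no positive eigenvalue")
  ev <- eg$values[seq_len(d)]
  A <- eg$vectors[, seq_len(d), drop = FALSE]
  # sign convention: largest-magnitude coefficient of each component positive
  for (j in seq_len(d)) {
    i <- which.max(abs(A[, j]))
    if (A[i, j] < 0) A[, j] <- -A[, j]
  }
  scale_ <- if (paper_literal_scaling) ev else sqrt(ev)
  alphas <- sweep(A, 2L, scale_, "/")
  model <- structure(list(train_vectors = X, alphas = alphas, eigvals = ev,
                          sigma = sigma, kernel = kernel,
                          poly_degree = poly_degree, d = d,
                          paper_literal_scaling = paper_literal_scaling,
                          literal_eq14 = literal_eq14, truncated = truncated,
                          K_colmeans = colMeans(K), K_grandmean = mean(K)),
                     class = "kpca_model")
  model$projections <- kpca_project(model, X)
  model
}

#' @export
print.kpca_model <- function(x, ...) {
  cat(sprintf("<kpca_model> %s kernel, %d components over %d training vectors\n",
              x$kernel, x$d, nrow(x$train_vectors)))
  if (x$kernel == "gaussian") cat(sprintf("  sigma = %g\n", x$sigma))
  cat("  eigenvalues:", paste(sprintf("%.4g", x$eigvals), collapse = " "), "\n")
  invisible(x)
}

#' Project vectors onto the kernel principal components
#'
#' Computes the kernel vector of each new point against the stored training
#' set, centers it against the training kernel statistics (unless the model
#' was fitted with `literal_eq14 = TRUE`), and applies the expansion
#' coefficients. Projecting a training vector reproduces its stored
#' training projection.
#'
#' @param model a `kpca_model`.
#' @param x a single vector or a matrix with vectors in rows, of the
#'   training dimensionality.
#' @return a length-`d` vector, or an m x d matrix for matrix input.
#' @export
kpca_project <- function(model, x) {
  single <- is.null(dim(x))
  Xn <- if (single) matrix(x, 1L) else as.matrix(x)
  if (ncol(Xn) != ncol(model$train_vectors))
    stop(sprintf("input has length %d, training vectors have %d",
                 ncol(Xn), ncol(model$train_vectors)))
  Kt <- .kernel_matrix(Xn, model$train_vectors, kernel = model$kernel,
                       sigma = model$sigma, degree = model$poly_degree)
  if (!model$literal_eq14) {
    n <- nrow(model$train_vectors)
    Kt <- Kt - matrix(model$K_colmeans, nrow(Kt), n, byrow = TRUE) -
      rowMeans(Kt) + model$K_grandmean
  }
  Z <- Kt %*% model$alphas
  if (single) drop(Z) else Z
}

#' @export
predict.kpca_model <- function(object, newdata, ...) kpca_project(object, newdata)
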