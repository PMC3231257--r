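#' Principal component analysis embedding
#'
#' Linear baseline: projects onto the top-d principal axes of the training
#' data (maximal retained variance). Backed by [stats::prcomp()].
#'
#' @param x numeric feature matrix, rows = samples.
#' @param d embedding dimension, `1 <= d <= min(N - 1, D)`.
#' @return An object of class `c("pca_embedding", "linear_embedding",
#'   "embedding")` with `center`, `rotation` (D x d, orthonormal columns),
#'   `values` (component variances) and `Y` (d x N training coordinates).
#' @export
pca_embed <- function(x, d) {
  x <- as.matrix(x)
  dmax <- min(nrow(x) - 1L, ncol(x))
  if (d < 1 || d > dmax)
    stop_invalid("d must satisfy 1 <= d <= ", dmax)
  p <- prcomp(x, center = TRUE, scale. = FALSE, rank. = d)
  rot <- fix_eigen_signs(p$rotation[, seq_len(d), drop = FALSE])
  Y <- t((x - matrix(p$center, nrow(x), ncol(x), byrow = TRUE)) %*% rot)
  structure(list(center = p$center, rotation = rot,
                 values = p$sdev[seq_len(d)]^2, Y = Y,
                 d = as.integer(d), method = "pca"),
            class = c("pca_embedding", "linear_embedding", "embedding"))
}

#' Fisher linear discriminant embedding
#'
#' Supervised linear baseline: directions maximizing the ratio of
#' between-class to within-class scatter. At most c - 1 meaningful
#' directions exist for c classes. For high-dimensional inputs (D >= N) the
#' problem is solved in the span of the centered training data (a principal
#' component basis of full rank) with a small ridge on the within-class
#' scatter, the standard remedy for its singularity.
#'
#' @param x numeric feature matrix, rows = samples.
#' @param labels class label per row.
#' @param d embedding dimension, `1 <= d <= (number of classes) - 1`.
#' @param ridge within-class scatter regularizer, as a fraction of its
#'   trace (default 1e-6).
#' @return An object of class `c("lda_embedding", "linear_embedding",
#'   "embedding")`; `rotation` maps centered features to coordinates.
#' @export
lda_embed <- function(x, labels, d, ridge = 1e-6) {
  x <- as.matrix(x)
  labels <- factor(labels)
  nc <- nlevels(labels)
  if (d < 1 || d > nc - 1)
    stop_invalid("LDA admits at most c - 1 = ", nc - 1, " dimensions")
  centre <- colMeans(x)
  xc <- x - matrix(centre, nrow(x), ncol(x), byrow = TRUE)
  # work in the span of the data when D is large
  r <- min(nrow(x) - 1L, ncol(x))
  if (ncol(x) > r) {
    sv <- svd(xc, nu = 0, nv = r)
    keep <- sv$d[seq_len(r)] > 1e-10 * sv$d[1]
    basis <- sv$v[, keep, drop = FALSE]
    z <- xc %*% basis
  } else {
    basis <- diag(ncol(x))
    z <- xc
  }
  Sw <- matrix(0, ncol(z), ncol(z))
  Sb <- matrix(0, ncol(z), ncol(z))
  for (lv in levels(labels)) {
    zi <- z[labels == lv, , drop = FALSE]
    mu <- colMeans(zi)
    Sw <- Sw + crossprod(zi - matrix(mu, nrow(zi), ncol(zi), byrow = TRUE))
    Sb <- Sb + nrow(zi) * tcrossprod(mu)
  }
  lam <- ridge * sum(diag(Sw)) / ncol(z)
  if (lam <= 0) lam <- 1e-8
  W <- solve(Sw + lam * diag(ncol(z)), Sb)
  e <- eigen(W)
  vecs <- Re(e$vectors[, seq_len(d), drop = FALSE])
  rot <- fix_eigen_signs(basis %*% vecs)
  Y <- t(xc %*% rot)
  structure(list(center = centre, rotation = rot,
                 values = Re(e$values[seq_len(d)]), Y = Y,
                 d = as.integer(d), method = "lda", labels = labels),
            class = c("lda_embedding", "linear_embedding", "embedding"))
}

#' Kernel principal component analysis embedding
#'
#' Nonlinear baseline: eigendecomposition of the double-centered kernel
#' matrix; coordinates are \eqn{\Lambda^{1/2} V^T} so embedded distances
#' approximate feature-space distances.
#'
#' @param x numeric feature matrix, rows = samples.
#' @param d embedding dimension, `1 <= d <= N`.
#' @param sigma Gaussian kernel bandwidth (default 1).
#' @param kernel `"gaussian"` (default) or `"linear"` (then KPCA coincides
#'   with PCA up to sign).
#' @return An object of class `c("kpca_embedding", "kernel_embedding",
#'   "embedding")` with the dual coefficients and training kernel
#'   statistics needed for out-of-sample projection.
#' @export
kpca_embed <- function(x, d, sigma = 1, kernel = c("gaussian", "linear")) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  n <- nrow(x)
  if (d < 1 || d > n) stop_invalid("d must satisfy 1 <= d <= N")
  K <- if (kernel == "gaussian") gaussian_kernel(x, sigma) else tcrossprod(x)
  Kc <- double_center_kernel(K)
  e <- eigen(Kc, symmetric = TRUE)
  vals <- pmax(e$values[seq_len(d)], 0)
  vecs <- fix_eigen_signs(e$vectors[, seq_len(d), drop = FALSE])
  Y <- diag(sqrt(vals), d) %*% t(vecs)
  structure(list(x = x, sigma = sigma, kernel = kernel,
                 values = vals, vectors = vecs, Y = Y,
                 K_colmeans = colMeans(K), K_mean = mean(K),
                 d = as.integer(d), method = "kpca"),
            class = c("kpca_embedding", "kernel_embedding", "embedding"))
}

# centering of a kernel matrix: HKH
double_center_kernel <- function(K) {
  n <- nrow(K)
  cm <- colMeans(K); gm <- mean(K)
  Kc <- K - matrix(cm, n, n, byrow = TRUE) - matrix(cm, n, n) + gm
  (Kc + t(Kc)) / 2
}

#' Kernel Fisher discriminant embedding (KLDA)
#'
#' Kernelized Fisher criterion in the dual: between-class and within-class
#' scatter are expressed through the kernel matrix, a ridge stabilizes the
#' within-class term (it is always singular in the dual), and the top
#' generalized eigenvectors give at most c - 1 discriminant coordinates.
#'
#' @inheritParams kpca_embed
#' @param labels class label per row.
#' @param ridge within-class dual scatter regularizer, as a fraction of its
#'   trace (default 1e-6).
#' @return An object of class `c("klda_embedding", "kernel_embedding",
#'   "embedding")`.
#' @export
klda_embed <- function(x, labels, d, sigma = 1, ridge = 1e-6) {
  x <- as.matrix(x)
  labels <- factor(labels)
  n <- nrow(x)
  nc <- nlevels(labels)
  if (d < 1 || d > nc - 1)
    stop_invalid("KLDA admits at most c - 1 = ", nc - 1, " dimensions")
  K <- gaussian_kernel(x, sigma)
  mstar <- rowMeans(K)
  B <- matrix(0, n, n)
  W <- matrix(0, n, n)
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    ni <- length(idx)
    mi <- rowMeans(K[, idx, drop = FALSE])
    B <- B + ni * tcrossprod(mi - mstar)
    Ki <- K[, idx, drop = FALSE]
    W <- W + Ki %*% (diag(ni) - 1 / ni) %*% t(Ki)
  }
  lam <- ridge * sum(diag(W)) / n
  if (lam <= 0) lam <- 1e-8
  e <- eigen(solve(W + lam * diag(n), B))
  A <- fix_eigen_signs(Re(e$vectors[, seq_len(d), drop = FALSE]))
  # normalize dual directions so training coordinates have unit scale
  A <- A / rep(sqrt(colSums(A^2)), each = n)
  Y <- t(K %*% A)
  structure(list(x = x, sigma = sigma, coef = A, Y = Y,
                 values = Re(e$values[seq_len(d)]),
                 d = as.integer(d), method = "klda", labels = labels),
            class = c("klda_embedding", "kernel_embedding", "embedding"))
}

#' Fit any of the compared embedding methods
#'
#' Front end dispatching to [pca_embed()], [lda_embed()], [kpca_embed()],
#' [klda_embed()], [kisomap()] or [kdisomap()]. Supervised methods require
#' `labels`.
#'
#' @param x numeric feature matrix, rows = samples.
#' @param method one of `"pca"`, `"lda"`, `"kpca"`, `"klda"`, `"kisomap"`,
#'   `"kdisomap"`.
#' @param d embedding dimension.
#' @param labels class labels (needed by lda, klda, kdisomap).
#' @param k neighbourhood size for the isomap variants.
#' @param sigma Gaussian bandwidth for the kernel methods.
#' @param alpha discriminant constant factor for kdisomap.
#' @param ... passed on to the method's fit function.
#' @return A fitted `embedding` object.
#' @export
fit_embedding <- function(x, method = c("pca", "lda", "kpca", "klda",
                                        "kisomap", "kdisomap"),
                          d = 2L, labels = NULL, k = 10L, sigma = 1,
                          alpha = 0.5, ...) {
  method <- match.arg(method)
  if (method %in% c("lda", "klda", "kdisomap") && is.null(labels))
    stop_invalid(method, " requires class labels")
  switch(method,
         pca = pca_embed(x, d, ...),
         lda = lda_embed(x, labels, d, ...),
         kpca = kpca_embed(x, d, sigma = sigma, ...),
         klda = klda_embed(x, labels, d, sigma = sigma, ...),
         kisomap = kisomap(x, d = d, k = k, ...),
         kdisomap = kdisomap(x, labels, d = d, k = k, sigma = sigma,
                             alpha = alpha, ...))
}

#' Project new points with a linear embedding
#'
#' @param object a fitted `pca_embedding` or `lda_embedding`.
#' @param xnew numeric matrix of new points (rows).
#' @param ... unused.
#' @return `d x M` coordinates.
#' @export
predict.linear_embedding <- function(object, xnew, ...) {
  xnew <- as.matrix(xnew)
  if (ncol(xnew) != length(object$center))
    stop_invalid("xnew must have ", length(object$center), " columns")
  if (nrow(xnew) == 0L) return(matrix(numeric(0), object$d, 0))
  xc <- xnew - matrix(object$center, nrow(xnew), ncol(xnew), byrow = TRUE)
  t(xc %*% object$rotation)
}

#' Project new points with a kernel embedding
#'
#' Kernel trick out-of-sample extension: kernel columns against the training
#' set are centered with the training statistics and projected onto the dual
#' directions.
#'
#' @param object a fitted `kpca_embedding` or `klda_embedding`.
#' @param xnew numeric matrix of new points (rows).
#' @param ... unused.
#' @return `d x M` coordinates.
#' @export
predict.kernel_embedding <- function(object, xnew, ...) {
  xnew <- as.matrix(xnew)
  if (ncol(xnew) != ncol(object$x))
    stop_invalid("xnew must have ", ncol(object$x), " columns")
  if (nrow(xnew) == 0L) return(matrix(numeric(0), object$d, 0))
  kx <- if (identical(object$kernel, "linear")) tcrossprod(xnew, object$x)
  else exp(-cross_dist(xnew, object$x)^2 / (2 * object$sigma^2))
  if (object$method == "kpca") {
    n <- ncol(kx)
    kc <- kx - matrix(object$K_colmeans, nrow(kx), n, byrow = TRUE) -
      rowMeans(kx) + object$K_mean
    lam <- object$values
    inv_sqrt <- ifelse(lam > 1e-12, 1 / sqrt(lam), 0)
    (diag(inv_sqrt, object$d) %*% t(object$vectors)) %*% t(kc)
  } else {
    t(kx %*% object$coef)
  }
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("%s embedding: d = %d, trained on %d samples\n",
              toupper(x$method), x$d, ncol(x$Y)))
  invisible(x)
}

#' @export
summary.embedding <- function(object, ...) {
  print(object)
  cat("  leading values:", paste(signif(head(object$values, 5), 4),
                                 collapse = ", "), "\n")
  invisible(object)
}
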