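#' Gaussian kernel matrix
#'
#' \eqn{\kappa(x_i, x_j) = \exp(-\|x_i - x_j\|^2 / 2\sigma^2)} over the rows
#' of a feature matrix. The bandwidth default \eqn{\sigma = 1} is the
#' conventional setting for LBP histogram features.
#'
#' @param x numeric matrix, rows = samples.
#' @param sigma kernel bandwidth (> 0).
#' @return Symmetric N x N matrix with unit diagonal, entries in (0, 1].
#' @export
gaussian_kernel <- function(x, sigma = 1) {
  x <- as.matrix(x)
  if (sigma <= 0) stop_invalid("sigma must be positive")
  if (any(!is.finite(x))) stop_invalid("features must be finite")
  d2 <- unname(as.matrix(dist(x)))^2
  K <- exp(-d2 / (2 * sigma^2))
  diag(K) <- 1
  K
}

#' Kernel Euclidean distance induced by a kernel matrix
#'
#' Distance between feature-space images,
#' \eqn{d_\kappa(x_i, x_j)^2 = \kappa(x_i, x_i) - 2\kappa(x_i, x_j) +
#' \kappa(x_j, x_j)}. For a Gaussian kernel this lies in [0, sqrt(2)).
#' Tiny negative squared distances from floating point (within 1e-12) are
#' clamped to zero; larger ones indicate a non-Mercer input and raise an
#' error.
#'
#' @param K symmetric kernel matrix.
#' @return Symmetric nonnegative matrix of distances with zero diagonal,
#'   attribute `kind = "kernel_euclidean"`.
#' @export
kernel_distance <- function(K) {
  K <- unname(as.matrix(K))
  if (nrow(K) != ncol(K)) stop_invalid("kernel matrix must be square")
  dk <- diag(K)
  d2 <- outer(dk, dk, "+") - 2 * K
  if (min(d2) < -1e-12)
    stop_invalid("negative squared kernel distance (", format(min(d2)),
                 "): input is not a valid Mercer kernel matrix")
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  attr(d, "kind") <- "kernel_euclidean"
  d
}

#' Average pairwise kernel distance (smoothing parameter beta)
#'
#' The smoothing parameter of the discriminant distance is tied to the data
#' density: beta is the mean kernel Euclidean distance over all unordered
#' sample pairs (self-pairs excluded).
#'
#' @param dk symmetric distance matrix (typically [kernel_distance()] output).
#' @return Positive scalar beta.
#' @export
pairwise_beta <- function(dk) {
  dk <- as.matrix(dk)
  n <- nrow(dk)
  if (n < 2L) stop_invalid("need at least two samples")
  beta <- mean(dk[upper.tri(dk)])
  if (beta <= 0)
    stop_invalid("all samples identical: beta = 0 is degenerate ",
                 "(the discriminant distance divides by beta)")
  beta
}

#' Kernel discriminant distance
#'
#' Label-aware dissimilarity in the reproducing kernel Hilbert space: for
#' samples with the same label \eqn{D = 1 - e^{-d^2/\beta}} (bounded in
#' [0, 1)), for different labels \eqn{D = e^{d^2/\beta} - \alpha}
#' (at least \eqn{1 - \alpha}). Both branches increase monotonically in the
#' kernel distance d, so the local geometry is preserved while interclass
#' pairs are pushed apart; at \eqn{\alpha = 0} every interclass dissimilarity
#' strictly exceeds every intraclass one. The two branches are intentionally
#' discontinuous across the class boundary — that gap is the discriminant
#' mechanism.
#'
#' @param dk kernel Euclidean distance matrix.
#' @param labels class label per sample (length N).
#' @param alpha constant factor in [0, 1] letting intraclass dissimilarities
#'   exceed interclass ones with some probability; default 0.5.
#' @param beta smoothing parameter (> 0), or `"auto"` for the
#'   [pairwise_beta()] average rule.
#' @return Symmetric matrix with attributes `kind = "discriminant"`,
#'   `alpha`, `beta`.
#' @export
discriminant_distance <- function(dk, labels, alpha = 0.5, beta = "auto") {
  dk <- unname(as.matrix(dk))
  n <- nrow(dk)
  if (length(labels) != n) stop_invalid("labels must match the matrix size")
  if (alpha < 0 || alpha > 1) stop_invalid("alpha must lie in [0, 1]")
  if (identical(beta, "auto")) beta <- pairwise_beta(dk)
  if (!is.numeric(beta) || beta <= 0) stop_invalid("beta must be positive")
  labels <- as.integer(factor(labels))
  same <- outer(labels, labels, "==")
  e <- exp(dk^2 / beta)
  D <- ifelse(same, 1 - 1 / e, e - alpha)
  diag(D) <- 0
  D <- (D + t(D)) / 2
  attr(D, "kind") <- "discriminant"
  attr(D, "alpha") <- alpha
  attr(D, "beta") <- beta
  D
}
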