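# Independent oracles used across the suite. Each reimplements the checked
# quantity by the most transparent route available (per-pixel loops,
# exhaustive enumeration, Floyd-Warshall, bisection), deliberately sharing no
# code with the package internals.

# per-pixel basic LBP: loop over interior pixels, threshold, accumulate bits
oracle_basic_lbp <- function(img) {
  h <- nrow(img); w <- ncol(img)
  off <- list(c(-1, 0), c(-1, -1), c(0, -1), c(1, -1),
              c(1, 0), c(1, 1), c(0, 1), c(-1, 1))
  out <- matrix(NA_real_, h - 2, w - 2)
  for (r in 2:(h - 1)) for (cc in 2:(w - 1)) {
    lab <- 0
    for (p in 0:7) {
      o <- off[[p + 1]]
      if (img[r + o[1], cc + o[2]] >= img[r, cc]) lab <- lab + 2^p
    }
    out[r - 1, cc - 1] <- lab
  }
  out
}

# per-pixel circular LBP with explicit bilinear interpolation at each point
oracle_circular_lbp <- function(img, P, R) {
  h <- nrow(img); w <- ncol(img)
  b <- ceiling(R)
  tol <- 1e-8 * max(1, max(abs(img)))
  out <- matrix(NA_real_, h - 2 * b, w - 2 * b)
  for (r in (b + 1):(h - b)) for (cc in (b + 1):(w - b)) {
    lab <- 0
    for (p in 0:(P - 1)) {
      th <- 2 * pi * p / P
      y <- r - R * cos(th); x <- cc - R * sin(th)
      y0 <- floor(y); x0 <- floor(x)
      fy <- y - y0; fx <- x - x0
      v <- (1 - fy) * (1 - fx) * img[y0, x0]
      if (fx > 0) v <- v + (1 - fy) * fx * img[y0, x0 + 1]
      if (fy > 0) v <- v + fy * (1 - fx) * img[y0 + 1, x0]
      if (fy > 0 && fx > 0) v <- v + fy * fx * img[y0 + 1, x0 + 1]
      if (v >= img[r, cc] - tol) lab <- lab + 2^p
    }
    out[r - b, cc - b] <- lab
  }
  out
}

# count circular 0/1 transitions of an integer's low P bits
oracle_transitions <- function(value, P) {
  bits <- as.integer(intToBits(value))[1:P]
  sum(bits != c(bits[-1], bits[1]))
}

# exhaustive count of uniform patterns for given P
oracle_uniform_count <- function(P) {
  sum(vapply(0:(2^P - 1), function(v) oracle_transitions(v, P) <= 2,
             logical(1)))
}

# Floyd-Warshall all-pairs shortest paths on a weight matrix (Inf = no edge)
oracle_floyd_warshall <- function(W) {
  n <- nrow(W)
  D <- W
  diag(D) <- 0
  for (k in seq_len(n)) {
    Dk <- outer(D[, k], D[k, ], "+")
    D <- pmin(D, Dk)
  }
  D
}

# weight matrix of a knn_graph for the oracle
graph_weight_matrix <- function(g) {
  W <- ifelse(g$adjacency, g$Dm, Inf)
  diag(W) <- 0
  W
}

# bisection on "min eigenvalue of K(D2) + 2cK(D) + c^2/2 H >= 0".
# The all-ones vector is an exact null direction of the shifted kernel for
# every c; it is lifted out of the spectrum so the sign test is not driven
# by rounding noise around zero.
oracle_shift_bisection <- function(KD2, KD, tol = 1e-9) {
  n <- nrow(KD2)
  H <- diag(n) - 1 / n
  scale <- max(1, max(abs(KD2)))
  lift <- matrix(scale / n, n, n)
  meig <- function(c)
    min(eigen(KD2 + 2 * c * KD + 0.5 * c^2 * H + lift, symmetric = TRUE,
              only.values = TRUE)$values)
  eps <- 1e-10 * scale
  if (meig(0) >= -eps) return(0)
  hi <- 1
  while (meig(hi) < -eps) hi <- hi * 2
  lo <- 0
  while (hi - lo > tol * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (meig(mid) >= -eps) hi <- mid else lo <- mid
  }
  hi
}

# exhaustive two-loop 1-NN
oracle_nn <- function(tr, trl, te) {
  out <- vector(class(trl[1]), nrow(te))
  idx <- integer(nrow(te))
  for (i in seq_len(nrow(te))) {
    best <- Inf; bj <- 1L
    for (j in seq_len(nrow(tr))) {
      d <- sum((te[i, ] - tr[j, ])^2)
      if (d < best) { best <- d; bj <- j }
    }
    idx[i] <- bj
  }
  trl[idx]
}

# element-wise two-loop Gaussian kernel
oracle_gaussian <- function(x, sigma) {
  n <- nrow(x)
  K <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- exp(-sum((x[i, ] - x[j, ])^2) / (2 * sigma^2))
  K
}

# a small random labeled dataset with class structure
random_labeled_data <- function(n_per = 8, n_classes = 3, dim = 4, sep = 2,
                                seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(n_classes), function(cl)
    matrix(rnorm(n_per * dim, mean = sep * cl), n_per, dim)))
  list(x = x, labels = rep(seq_len(n_classes), each = n_per))
}
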