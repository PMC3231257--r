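#' k-nearest-neighbour graph from a dissimilarity matrix
#'
#' Connects each sample to its `k` smallest-dissimilarity neighbours (ties
#' broken by smaller sample index) and symmetrizes by union: an edge exists
#' when either endpoint selects the other, so every node ends with degree at
#' least `k`. Edge weights are the input dissimilarities.
#'
#' @param Dm symmetric nonnegative dissimilarity matrix.
#' @param k neighbours per node, `1 <= k < N`.
#' @return An object of class `knn_graph`: list with `adjacency` (logical
#'   N x N), `weights` (numeric N x N, `NA` where no edge), `k`, `Dm` and
#'   `graph` (an igraph object used for shortest paths).
#' @export
knn_graph <- function(Dm, k) {
  Dm <- unname(as.matrix(Dm))
  n <- nrow(Dm)
  if (n != ncol(Dm)) stop_invalid("dissimilarity matrix must be square")
  if (k < 1 || k >= n) stop_invalid("k must satisfy 1 <= k < N (N = ", n, ")")
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    d <- Dm[i, ]
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(k)]  # stable: ties -> smaller index
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)                       # union symmetrization
  diag(adj) <- FALSE
  w <- ifelse(adj, Dm, NA_real_)
  g <- igraph::graph_from_adjacency_matrix(adj * Dm, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  # zero-weight edges vanish in the weighted adjacency; restore them
  missing <- which(adj & upper.tri(adj) & Dm == 0, arr.ind = TRUE)
  if (nrow(missing) > 0) {
    g <- igraph::add_edges(g, t(missing), weight = 0)
    g <- igraph::simplify(g, edge.attr.comb = list(weight = "min"))
  }
  structure(list(adjacency = adj, weights = w, k = as.integer(k),
                 Dm = Dm, graph = g),
            class = "knn_graph")
}

#' @export
print.knn_graph <- function(x, ...) {
  cat(sprintf("k-NN graph: %d nodes, %d edges, k = %d\n",
              nrow(x$adjacency), sum(x$adjacency) / 2, x$k))
  invisible(x)
}

#' All-pairs geodesic distances over a neighbourhood graph
#'
#' Shortest-path lengths between every pair of nodes (Dijkstra's algorithm
#' via igraph), approximating manifold geodesic distances. A disconnected
#' graph is an error naming the component sizes, unless `auto_connect` is
#' set, in which case the single shortest inter-component dissimilarity edge
#' is added repeatedly until the graph is connected.
#'
#' @param g a [knn_graph()] object.
#' @param auto_connect bridge disconnected components instead of failing
#'   (default `FALSE`).
#' @return Symmetric matrix of shortest-path distances, zero diagonal,
#'   attribute `kind = "geodesic"`.
#' @export
geodesic_distances <- function(g, auto_connect = FALSE) {
  stopifnot(inherits(g, "knn_graph"))
  graph <- g$graph
  comp <- igraph::components(graph)
  if (comp$no > 1L) {
    if (!auto_connect) {
      sizes <- paste(sort(comp$csize, decreasing = TRUE), collapse = ", ")
      stop_invalid("neighbourhood graph is disconnected (", comp$no,
                   " components of sizes ", sizes, "). Increase k, or pass ",
                   "auto_connect = TRUE to bridge components with their ",
                   "shortest inter-component edge.")
    }
    while (comp$no > 1L) {
      memb <- comp$membership
      cross <- outer(memb, memb, "!=")
      Dm <- g$Dm
      Dm[!cross] <- Inf
      ij <- which(Dm == min(Dm), arr.ind = TRUE)[1, ]
      graph <- igraph::add_edges(graph, ij, weight = g$Dm[ij[1], ij[2]])
      comp <- igraph::components(graph)
    }
  }
  D <- igraph::distances(graph, algorithm = "dijkstra",
                         weights = igraph::E(graph)$weight)
  dimnames(D) <- NULL
  D <- (D + t(D)) / 2
  diag(D) <- 0
  attr(D, "kind") <- "geodesic"
  D
}

#' Double centering of a (squared) distance matrix
#'
#' The classical-MDS map \eqn{K(M) = -\frac{1}{2} H M H} with centering
#' matrix \eqn{H = I - \frac{1}{N} e e^T}, turning squared distances into a
#' Gram matrix. Every row and column of the result sums to zero.
#'
#' @param M square symmetric matrix (squared or first-power distances).
#' @return Centered kernel matrix of the same size.
#' @export
double_center <- function(M) {
  M <- unname(as.matrix(M))
  if (nrow(M) != ncol(M)) stop_invalid("input must be square")
  rm_ <- rowMeans(M); cm <- colMeans(M); gm <- mean(M)
  K <- -0.5 * (M - outer(rm_, rep(1, ncol(M))) -
                 outer(rep(1, nrow(M)), cm) + gm)
  (K + t(K)) / 2
}

#' Smallest constant shift making the geodesic kernel a Mercer kernel
#'
#' The doubly centered geodesic kernel is not always positive semi-definite;
#' adding a constant c to every off-diagonal geodesic distance fixes this
#' for all c at or above a critical value c*, the largest eigenvalue of the
#' 2N x 2N block matrix
#' \deqn{\begin{pmatrix} 0 & 2K(D^2) \\ -I & -4K(D) \end{pmatrix}.}
#' Eigenvalues of this non-symmetric matrix may acquire tiny imaginary parts
#' in floating point; the largest real part is selected and, if its
#' imaginary part is not negligible, the routine falls back to bisection on
#' the condition "minimum eigenvalue of K*(c) is nonnegative".
#'
#' @param KD2 double-centered squared geodesic matrix, \eqn{-\frac12 H D^2 H}.
#' @param KD double-centered first-power geodesic matrix, \eqn{-\frac12 H D H}.
#' @return The critical shift c* (a real scalar, possibly negative when the
#'   centered kernel is already positive semi-definite).
#' @export
shift_constant <- function(KD2, KD) {
  KD2 <- as.matrix(KD2); KD <- as.matrix(KD)
  n <- nrow(KD2)
  stopifnot(ncol(KD2) == n, nrow(KD) == n, ncol(KD) == n)
  B <- rbind(cbind(matrix(0, n, n), 2 * KD2),
             cbind(-diag(n), -4 * KD))
  ev <- tryCatch(eigen(B, only.values = TRUE)$values,
                 error = function(e) NULL)
  if (!is.null(ev)) {
    re <- Re(ev); im <- Im(ev)
    i <- which.max(re)
    if (abs(im[i]) < 1e-6 * max(1, abs(re[i]))) return(re[i])
  }
  psd_shift_bisection(KD2, KD)
}

# fallback: bisection for the smallest c >= 0 with K*(c) PSD. The all-ones
# direction is a structural null vector of K*(c) for every c (H e = 0), so
# it is deflated before taking the minimum eigenvalue; otherwise the PSD
# test flips on +/- 1e-15 noise around that exact zero.
psd_shift_bisection <- function(KD2, KD, tol = 1e-9) {
  n <- nrow(KD2)
  scale <- max(1, max(abs(KD2)))
  deflate <- matrix(scale / n, n, n)
  min_eig <- function(c) {
    min(eigen(mercer_kernel(KD2, KD, c) + deflate, symmetric = TRUE,
              only.values = TRUE)$values)
  }
  eps <- 1e-10 * scale
  if (min_eig(0) >= -eps) return(0)
  hi <- 1
  while (min_eig(hi) < -eps) hi <- hi * 2
  lo <- 0
  while (hi - lo > tol * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (min_eig(mid) >= -eps) hi <- mid else lo <- mid
  }
  hi
}

#' Constant-shifted Mercer kernel from centered geodesic matrices
#'
#' \deqn{K^* = K(D^2) + 2c\,K(D) + \tfrac{1}{2} c^2 H,}
#' guaranteed positive semi-definite for every c at or above the critical
#' shift of [shift_constant()]. Equivalently, K* is the double-centered
#' squared version of the geodesic matrix with c added to every off-diagonal
#' entry.
#'
#' @param KD2,KD double-centered squared / first-power geodesic matrices.
#' @param c shift constant.
#' @param cstar optional critical shift; a warning is issued when `c < cstar`.
#' @return Symmetric N x N kernel matrix.
#' @export
mercer_kernel <- function(KD2, KD, c, cstar = NULL) {
  n <- nrow(KD2)
  if (!is.null(cstar) && c < cstar - 1e-12)
    warning("c < c*: the shifted kernel need not be positive semi-definite")
  H <- diag(n) - 1 / n
  K <- KD2 + 2 * c * KD + 0.5 * c^2 * H
  (K + t(K)) / 2
}

#' Spectral embedding of a Mercer kernel matrix
#'
#' Top-d eigendecomposition of K* and the classical-MDS coordinate read-out
#' \eqn{Y = \Lambda^{1/2} V^T}. Negative retained eigenvalues are clamped to
#' zero with a warning (their directions carry no coordinates). Eigenvector
#' signs are fixed by making each vector's largest-magnitude entry positive,
#' so embeddings are reproducible across eigensolvers.
#'
#' @param Kstar symmetric kernel matrix.
#' @param d embedding dimension, `1 <= d <= N`.
#' @return List with `values` (top-d eigenvalues, non-increasing), `vectors`
#'   (N x d, orthonormal columns) and `Y` (d x N coordinates).
#' @export
spectral_embed <- function(Kstar, d) {
  Kstar <- as.matrix(Kstar)
  n <- nrow(Kstar)
  if (d < 1 || d > n) stop_invalid("d must satisfy 1 <= d <= N")
  e <- eigen(Kstar, symmetric = TRUE)
  vals <- e$values[seq_len(d)]
  vecs <- e$vectors[, seq_len(d), drop = FALSE]
  vecs <- fix_eigen_signs(vecs)
  if (any(vals < 0)) {
    if (any(vals < -1e-8 * max(1, abs(e$values[1]))))
      warning("negative eigenvalues clamped to zero in the embedding")
    vals[vals < 0] <- 0
  }
  Y <- diag(sqrt(vals), d) %*% t(vecs)
  list(values = vals, vectors = vecs, Y = Y)
}

fix_eigen_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

# shared isomap pipeline on a precomputed dissimilarity matrix
isomap_core <- function(Dm, d, k, shift = c("none", "mercer"),
                        auto_connect = FALSE) {
  shift <- match.arg(shift)
  g <- knn_graph(Dm, k)
  G <- geodesic_distances(g, auto_connect = auto_connect)
  KD2 <- double_center(G^2)
  KD <- double_center(G)
  if (shift == "mercer") {
    ev2 <- eigen(KD2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev2) >= -1e-8 * max(1, abs(ev2[1]))) {
      cstar <- 0                # already PSD: no shift needed, skip the 2N solve
    } else {
      cstar <- shift_constant(KD2, KD)
    }
    cc <- max(cstar, 0)
  } else {
    cstar <- NA_real_           # not computed: classical (unshifted) embedding
    cc <- 0
  }
  Kstar <- mercer_kernel(KD2, KD, cc)
  se <- spectral_embed(Kstar, d)
  list(graph = g, geodesic = G, KD2 = KD2, KD = KD, cstar = cstar, c = cc,
       Kstar = Kstar, values = se$values, vectors = se$vectors, Y = se$Y,
       shift = shift)
}

#' Kernel isometric mapping (unsupervised)
#'
#' Isomap with a kernel-style out-of-sample extension: build a k-NN graph on
#' Euclidean distances, approximate geodesic distances by graph shortest
#' paths, double-center the squared geodesic matrix, and embed through its
#' top-d eigenvectors; new points are then projected by the kernel trick
#' without refitting (see [predict.isomap_embedding()]).
#'
#' By default (`shift = "none"`) the embedding is the classical one: the
#' centered geodesic kernel may have negative eigenvalues (graph geodesics
#' are not exactly Euclidean) and any negative retained eigenvalue is
#' clamped to zero, which keeps the low-dimensional geometry undistorted.
#' `shift = "mercer"` instead applies the constant-shifting construction —
#' every off-diagonal geodesic distance is increased by `c = max(c*, 0)`
#' ([shift_constant()]) so the full kernel matrix is positive semi-definite
#' (a Mercer kernel). The shift buys an all-nonnegative spectrum at the cost
#' of adding c to every pairwise distance, a measurable distortion of
#' low-dimensional isometry, which is why it is opt-in.
#'
#' @param x numeric feature matrix, rows = samples.
#' @param d embedding dimension.
#' @param k neighbours for the graph (default 10).
#' @param shift `"none"` (default, classical embedding) or `"mercer"`
#'   (constant shift `c = max(c*, 0)`).
#' @param auto_connect bridge disconnected graph components (default
#'   `FALSE`; the error message suggests raising `k`).
#' @return An object of class `c("kisomap", "isomap_embedding", "embedding")`
#'   with components `Y` (d x N coordinates), `values`, `vectors`, `cstar`,
#'   `c`, `geodesic`, `k`, `d` and the training data needed by `predict`.
#' @seealso [kdisomap()] for the supervised variant.
#' @examples
#' sr <- make_swiss_roll(200, seed = 1)
#' fit <- kisomap(sr$points, d = 2, k = 8)
#' fit
#' @export
kisomap <- function(x, d = 2L, k = 10L, shift = c("none", "mercer"),
                    auto_connect = FALSE) {
  x <- as.matrix(x)
  Dm <- as.matrix(dist(x))
  core <- isomap_core(Dm, d = d, k = k, shift = shift,
                      auto_connect = auto_connect)
  structure(c(core,
              list(x = x, d = as.integer(d), k = as.integer(k),
                   method = "kisomap")),
            class = c("kisomap", "isomap_embedding", "embedding"))
}

#' Kernel discriminant isometric mapping (supervised)
#'
#' KDIsomap replaces the Euclidean edge lengths of kernel Isomap with a
#' kernel discriminant distance: features are mapped into a reproducing
#' kernel Hilbert space by a Gaussian kernel, the kernel Euclidean distance
#' is transformed so that same-class pairs are compressed
#' (\eqn{1 - e^{-d^2/\beta}}) and different-class pairs expanded
#' (\eqn{e^{d^2/\beta} - \alpha}), and the geodesic/constant-shift/spectral
#' machinery of [kisomap()] runs on the result. This maximizes interclass
#' scatter while minimizing intraclass scatter along the manifold, giving
#' discriminant low-dimensional coordinates.
#'
#' @inheritParams kisomap
#' @param labels class label per row of `x`.
#' @param sigma Gaussian kernel bandwidth (default 1).
#' @param alpha discriminant constant factor in [0, 1] (default 0.5); 0
#'   guarantees every interclass dissimilarity exceeds every intraclass one.
#' @param beta smoothing parameter, or `"auto"` (default) for the average
#'   pairwise kernel distance rule.
#' @return An object of class
#'   `c("kdisomap", "isomap_embedding", "embedding")`; components as in
#'   [kisomap()] plus `labels`, `sigma`, `alpha`, `beta`. Out-of-sample
#'   projection ([predict.isomap_embedding()]) cannot use the label-dependent
#'   distance for unlabeled test points; it uses the bounded intraclass
#'   transform of the kernel distance for test-to-training edges (recorded
#'   in `oos_rule`).
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(100), 50), matrix(rnorm(100, 2), 50))
#' y <- rep(c("a", "b"), each = 50)
#' fit <- kdisomap(x, y, d = 2, k = 10, alpha = 0)
#' summary(fit)
#' @export
kdisomap <- function(x, labels, d = 2L, k = 10L, sigma = 1, alpha = 0.5,
                     beta = "auto", shift = c("none", "mercer"),
                     auto_connect = FALSE) {
  x <- as.matrix(x)
  if (length(labels) != nrow(x)) stop_invalid("labels must match rows of x")
  K <- gaussian_kernel(x, sigma = sigma)
  dk <- kernel_distance(K)
  if (identical(beta, "auto")) beta <- pairwise_beta(dk)
  Dm <- discriminant_distance(dk, labels, alpha = alpha, beta = beta)
  core <- isomap_core(Dm, d = d, k = k, shift = shift,
                      auto_connect = auto_connect)
  structure(c(core,
              list(x = x, labels = labels, d = as.integer(d), k = as.integer(k),
                   sigma = sigma, alpha = alpha, beta = beta,
                   method = "kdisomap",
                   oos_rule = "intraclass transform of kernel distance")),
            class = c("kdisomap", "isomap_embedding", "embedding"))
}

# dissimilarity from M new points (rows of xnew) to the N training points,
# matching the metric the model's graph was built with (up to the
# label-free surrogate for kdisomap)
oos_dissimilarity <- function(object, xnew) {
  if (object$method == "kisomap") {
    cross_dist(xnew, object$x)
  } else {
    d2 <- cross_dist(xnew, object$x)^2
    kx <- exp(-d2 / (2 * object$sigma^2))
    dk2 <- pmax(2 - 2 * kx, 0)
    1 - exp(-dk2 / object$beta)           # bounded intraclass branch
  }
}

cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Project new points into a fitted isometric embedding
#'
#' Out-of-sample extension by the kernel trick: each new point is linked to
#' its k nearest training points, its geodesic distance to every training
#' point is the minimum over those links of (edge length + training
#' geodesic), the resulting squared-distance column is shifted by the model
#' constant c and centered with the training statistics, and the coordinates
#' are read out as \eqn{y = \Lambda^{-1/2} V^T \tilde{k}}. Training points
#' passed back through reproduce their training coordinates. For KDIsomap
#' the test-to-training edge lengths use the bounded intraclass transform of
#' the kernel Euclidean distance, since a test point's label is unknown.
#'
#' @param object a fitted [kisomap()] or [kdisomap()] model.
#' @param xnew numeric matrix of new points (rows), with the training
#'   feature dimension; zero rows give an empty `d x 0` result.
#' @param ... unused.
#' @return `d x M` matrix of embedded coordinates.
#' @export
predict.isomap_embedding <- function(object, xnew, ...) {
  xnew <- as.matrix(xnew)
  if (ncol(xnew) == 1L && ncol(object$x) > 1L && nrow(xnew) == ncol(object$x))
    xnew <- t(xnew)
  if (ncol(xnew) != ncol(object$x))
    stop_invalid("xnew must have ", ncol(object$x), " columns")
  d <- object$d
  if (nrow(xnew) == 0L) return(matrix(numeric(0), d, 0))
  e <- oos_dissimilarity(object, xnew)        # M x N edge candidates
  G <- object$geodesic
  n <- ncol(e)
  kk <- min(object$k, n)
  # constant shift acts on off-diagonal distances; a new point is distinct
  # from every training point, so shift every entry
  Ds2 <- (G + object$c)^2
  diag(Ds2) <- 0
  # geodesic of each new point to every training point: through its k
  # nearest training neighbours only; a point coinciding with training
  # point i inherits i's geodesic profile exactly (self-consistency)
  snap_tol <- 1e-8 * max(1, max(G))
  gs2 <- matrix(Inf, nrow(e), n)
  for (m in seq_len(nrow(e))) {
    nb <- order(e[m, ], seq_len(n))[seq_len(kk)]
    if (e[m, nb[1]] <= snap_tol) {
      gs2[m, ] <- Ds2[nb[1], ]
    } else {
      g <- do.call(pmin, lapply(nb, function(j) e[m, j] + G[j, ]))
      gs2[m, ] <- (g + object$c)^2
    }
  }
  colm <- colMeans(Ds2); gm <- mean(Ds2)
  kt <- -0.5 * (gs2 - rowMeans(gs2) -
                  matrix(colm, nrow(gs2), n, byrow = TRUE) + gm)
  lam <- object$values
  inv_sqrt <- ifelse(lam > 1e-12, 1 / sqrt(lam), 0)
  Y <- (diag(inv_sqrt, d) %*% t(object$vectors)) %*% t(kt)
  Y
}

#' @export
print.isomap_embedding <- function(x, ...) {
  cat(sprintf("%s embedding: N = %d, d = %d, k = %d\n",
              if (x$method == "kdisomap") "Kernel discriminant Isomap"
              else "Kernel Isomap",
              ncol(x$Y), x$d, x$k))
  if (identical(x$shift, "mercer"))
    cat(sprintf("  Mercer constant shift c = %.6g (critical c* = %.6g)\n",
                x$c, x$cstar))
  else
    cat("  classical (unshifted) embedding\n")
  if (x$method == "kdisomap")
    cat(sprintf("  sigma = %g, alpha = %g, beta = %.6g\n",
                x$sigma, x$alpha, x$beta))
  invisible(x)
}

#' @export
summary.isomap_embedding <- function(object, ...) {
  print(object)
  ev <- object$values
  cat("  top eigenvalues:", paste(signif(head(ev, 5), 4), collapse = ", "), "\n")
  invisible(object)
}

#' @export
fitted.embedding <- function(object, ...) t(object$Y)

#' Scatterplot of the first two embedded coordinates
#'
#' @param x a fitted embedding.
#' @param labels optional point labels for colouring; defaults to the
#'   training labels when the model has them.
#' @param ... passed to [graphics::plot()].
#' @export
plot.embedding <- function(x, labels = NULL, ...) {
  Y <- t(x$Y)
  if (ncol(Y) < 2) stop_invalid("need at least 2 embedded dimensions to plot")
  if (is.null(labels)) labels <- x$labels
  col <- if (is.null(labels)) "black"
  else hcl.colors(nlevels(factor(labels)), "Dark 3")[as.integer(factor(labels))]
  plot(Y[, 1], Y[, 2], col = col, pch = 19,
       xlab = "dimension 1", ylab = "dimension 2", ...)
  if (!is.null(labels))
    legend("topright", legend = levels(factor(labels)), col =
             hcl.colors(nlevels(factor(labels)), "Dark 3"), pch = 19, cex = 0.8)
  invisible(x)
}
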