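test_that("knn graphs connect nearest neighbours with union symmetrization", {
  # 3 collinear points, k = 1: middle point bridges the ends
  Dm <- as.matrix(dist(c(0, 1, 2.5)))
  g <- knn_graph(Dm, 1)
  expect_true(g$adjacency[1, 2] && g$adjacency[2, 3])
  expect_false(g$adjacency[1, 3])

  set.seed(41)
  Dm2 <- as.matrix(dist(matrix(rnorm(30), 10, 3)))
  g2 <- knn_graph(Dm2, 9)                 # k = N - 1: complete graph
  expect_true(all(g2$adjacency[upper.tri(g2$adjacency)]))

  g3 <- knn_graph(Dm2, 3)
  expect_true(all(rowSums(g3$adjacency) >= 3))   # degree >= k after union
  expect_true(all(diag(g3$adjacency) == FALSE))
  expect_error(knn_graph(Dm2, 10), "k must satisfy")
})

test_that("geodesic distances equal shortest paths", {
  # path graph with edge weights 1 and 2
  Dm <- as.matrix(dist(c(0, 1, 3)))
  g <- knn_graph(Dm, 1)
  G <- geodesic_distances(g)
  expect_equal(G[1, 3], 3)
  expect_equal(diag(G), rep(0, 3))

  # random connected graphs vs Floyd-Warshall oracle
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(8:12, 1)
    Dm2 <- as.matrix(dist(matrix(rnorm(3 * n), n, 3)))
    g2 <- knn_graph(Dm2, 4)
    G2 <- geodesic_distances(g2)
    expect_equal(G2, oracle_floyd_warshall(graph_weight_matrix(g2)),
                 tolerance = 1e-10, ignore_attr = TRUE)
    # direct edges are never exceeded
    W <- graph_weight_matrix(g2)
    expect_true(all(G2[is.finite(W)] <= W[is.finite(W)] + 1e-12))
  }
})

test_that("disconnected graphs raise an actionable error or are bridged", {
  x <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
             matrix(rnorm(20, 50, 0.1), 10, 2))
  Dm <- as.matrix(dist(x))
  g <- knn_graph(Dm, 3)
  expect_error(geodesic_distances(g), "disconnected.*Increase k")
  G <- geodesic_distances(g, auto_connect = TRUE)
  expect_true(all(is.finite(G)))
  expect_true(isSymmetric(unname(G)))
})

test_that("double centering annihilates row sums and matches hand arithmetic", {
  a <- 3
  D2 <- matrix(c(0, a^2, a^2, 0), 2)
  expect_equal(double_center(D2),
               matrix(c(a^2 / 4, -a^2 / 4, -a^2 / 4, a^2 / 4), 2))

  expect_equal(double_center(matrix(0, 4, 4)), matrix(0, 4, 4))

  set.seed(43)
  for (i in 1:5) {
    M <- as.matrix(dist(matrix(rnorm(24), 8, 3)))^2
    K <- double_center(M)
    expect_true(all(abs(rowSums(K)) < 1e-10))
    expect_true(all(abs(colSums(K)) < 1e-10))
    expect_true(isSymmetric(K))
  }
})

test_that("block-matrix critical shift agrees with the bisection oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- matrix(rnorm(30), 10, 3)
    g <- knn_graph(as.matrix(dist(x)), 4)
    G <- geodesic_distances(g, auto_connect = TRUE)
    KD2 <- double_center(G^2); KD <- double_center(G)
    cs <- shift_constant(KD2, KD)
    cb <- oracle_shift_bisection(KD2, KD)
    expect_equal(max(cs, 0), cb, tolerance = 1e-6)
  }
})

test_that("the shifted kernel is positive semi-definite at and above c*", {
  set.seed(47)
  x <- matrix(rnorm(36), 12, 3)
  G <- geodesic_distances(knn_graph(as.matrix(dist(x)), 4),
                          auto_connect = TRUE)
  KD2 <- double_center(G^2); KD <- double_center(G)
  cs <- max(shift_constant(KD2, KD), 0)
  for (extra in c(0, 0.1, 1, 10)) {
    mk <- mercer_kernel(KD2, KD, cs + extra)
    mev <- min(eigen(mk, symmetric = TRUE, only.values = TRUE)$values)
    expect_gt(mev, -1e-8 * max(1, cs^2))
  }
  # c = 0 reproduces the centered squared-geodesic kernel exactly
  expect_equal(mercer_kernel(KD2, KD, 0), KD2)
  expect_warning(mercer_kernel(KD2, KD, cs - 1, cstar = cs), "c < c\\*")
})

test_that("spectral embedding satisfies the classical-MDS closed forms", {
  # two points at geodesic distance a: coordinates +/- a/2
  a <- 4
  K2 <- double_center(matrix(c(0, a^2, a^2, 0), 2))
  se <- spectral_embed(K2, 1)
  expect_equal(sort(as.vector(se$Y)), c(-a / 2, a / 2), tolerance = 1e-10)

  set.seed(53)
  x <- matrix(rnorm(40), 10, 4)
  K <- tcrossprod(scale(x, scale = FALSE))       # PSD Gram
  se2 <- spectral_embed(K, 10)
  expect_equal(crossprod(se2$Y), K, tolerance = 1e-6)   # full-rank recovery
  expect_true(all(diff(se2$values) <= 1e-10))    # non-increasing
  # rank-d Gram identity
  se3 <- spectral_embed(K, 3)
  proj <- se3$vectors %*% diag(se3$values) %*% t(se3$vectors)
  expect_equal(crossprod(se3$Y), proj, tolerance = 1e-6)
  expect_error(spectral_embed(K, 11), "1 <= d <= N")
})

test_that("kisomap recovers flat manifolds isometrically", {
  # points on a 2-D plane embedded in 10-D. Graph shortest paths between
  # non-adjacent samples overestimate straight lines by a few percent (the
  # intrinsic stretch of k-NN graph paths), so pointwise agreement is tested
  # at that accuracy while direct edges are exact.
  set.seed(59)
  uv <- matrix(runif(2000, 0, 5), 1000, 2)
  basis <- qr.Q(qr(matrix(rnorm(20), 10, 2)))
  x <- uv %*% t(basis)
  fit <- kisomap(x, d = 2, k = 10)
  ed <- as.vector(dist(t(fit$Y)))
  td <- as.vector(dist(uv))
  expect_gt(cor(ed, td), 0.999)
  expect_lt(median(abs(ed - td) / td), 0.05)
  # geodesics along direct graph edges equal the plane distances exactly
  A <- fit$graph$adjacency
  idx <- which(A & upper.tri(A), arr.ind = TRUE)
  tdm <- as.matrix(dist(uv))
  expect_lt(max(abs(fit$geodesic[idx] - tdm[idx])), 1e-10)
})

test_that("kisomap respects sample-order equivariance", {
  set.seed(61)
  sr <- make_swiss_roll(80, seed = 5)
  fit <- kisomap(sr$points, d = 2, k = 8)
  p <- sample(80)
  fitp <- kisomap(sr$points[p, ], d = 2, k = 8)
  # same embedded geometry: pairwise distances identical under the permutation
  D1 <- unname(as.matrix(dist(t(fit$Y))))
  D2 <- unname(as.matrix(dist(t(fitp$Y))))
  expect_equal(D2, unname(D1[p, p]), tolerance = 1e-8)
})

test_that("single-class kdisomap ranks neighbours like the kernel distance", {
  set.seed(67)
  x <- matrix(rnorm(100), 25, 4)
  labs <- rep(1, 25)
  fit <- kdisomap(x, labs, d = 2, k = 6, alpha = 0.9)
  dk <- kernel_distance(gaussian_kernel(x, 1))
  # the intraclass branch is a monotone transform of d_k: the k-NN sets of
  # the discriminant matrix match those of the kernel distance
  for (i in 1:25) {
    nb_fit <- which(fit$graph$adjacency[i, ])
    d <- dk[i, ]; d[i] <- Inf
    nb_dk <- order(d)[1:6]
    expect_true(all(nb_dk %in% union(nb_fit, i)))
  }
})

test_that("supervision helps on separable classes (kdisomap vs kisomap)", {
  accs <- vapply(1:10, function(seed) {
    set.seed(seed)
    n <- 30
    x <- rbind(matrix(rnorm(n * 5, 0), n, 5), matrix(rnorm(n * 5, 2), n, 5))
    y <- rep(c(1, 2), each = n)
    tr <- c(1:20, 31:50); te <- setdiff(1:60, tr)
    fd <- kdisomap(x[tr, ], y[tr], d = 2, k = 10, alpha = 0,
                   auto_connect = TRUE)
    fi <- kisomap(x[tr, ], d = 2, k = 10, auto_connect = TRUE)
    c(mean(nn_classify(fd$Y, y[tr], predict(fd, x[te, ])) == y[te]),
      mean(nn_classify(fi$Y, y[tr], predict(fi, x[te, ])) == y[te]))
  }, numeric(2))
  expect_gte(mean(accs[1, ]) - mean(accs[2, ]), 0)
})

test_that("out-of-sample projection is self-consistent", {
  sr <- make_swiss_roll(60, seed = 3)
  for (shift in c("none", "mercer")) {
    fit <- kisomap(sr$points, d = 2, k = 8, shift = shift)
    expect_equal(predict(fit, sr$points), fit$Y, tolerance = 1e-6)
    # duplicate of training point 7
    expect_equal(as.vector(predict(fit, sr$points[7, , drop = FALSE])),
                 as.vector(fit$Y[, 7]), tolerance = 1e-6)
  }
  dat <- random_labeled_data(n_per = 10, seed = 71)
  fd <- kdisomap(dat$x, dat$labels, d = 3, k = 8, alpha = 0.5,
                 auto_connect = TRUE)
  expect_equal(predict(fd, dat$x), fd$Y, tolerance = 1e-6)
  # empty input: d x 0, no error
  empty <- predict(fd, dat$x[0, , drop = FALSE])
  expect_equal(dim(empty), c(3L, 0L))
  expect_error(predict(fd, matrix(1, 2, 3)), "columns")
})

test_that("embedding output dimensions follow the contract", {
  dat <- random_labeled_data(seed = 73)
  fit <- kdisomap(dat$x, dat$labels, d = 4, k = 8, auto_connect = TRUE)
  expect_equal(dim(fit$Y), c(4L, nrow(dat$x)))
  expect_true(all(fit$values >= 0))
  expect_equal(crossprod(fit$vectors), diag(4), tolerance = 1e-8)
})
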