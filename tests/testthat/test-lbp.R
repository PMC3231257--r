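test_that("basic LBP handles the degenerate threshold cases", {
  img <- matrix(100, 5, 5)
  expect_true(all(basic_lbp(img)$labels == 255))  # neighbour >= centre on ties

  img2 <- matrix(0, 3, 3)
  img2[2, 2] <- 200
  expect_equal(basic_lbp(img2)$labels[1, 1], 0)

  expect_error(basic_lbp(matrix(1, 2, 3)), "at least")
})

test_that("basic LBP matches the per-pixel brute-force oracle", {
  set.seed(42)
  for (rep in 1:3) {
    img <- matrix(sample(0:255, 35, replace = TRUE), 5, 7)
    expect_equal(unname(basic_lbp(img)$labels), oracle_basic_lbp(img))
  }
})

test_that("circular LBP matches the per-pixel oracle for (8,1), (8,2), (16,2)", {
  set.seed(7)
  for (pr in list(c(8, 1), c(8, 2), c(16, 2))) {
    img <- matrix(sample(0:255, 81, replace = TRUE), 9, 9)
    got <- circular_lbp(img, P = pr[1], R = pr[2])$labels
    expect_equal(unname(got), oracle_circular_lbp(img, pr[1], pr[2]),
                 label = sprintf("(P,R)=(%d,%d)", pr[1], pr[2]))
  }
  # ramp image, explicitly non-constant gradients
  ramp <- outer(1:9, 1:9, function(a, b) 3 * a + 2 * b)
  expect_equal(unname(circular_lbp(ramp, 8, 2)$labels),
               oracle_circular_lbp(ramp, 8, 2))
})

test_that("constant images give the all-ones pattern for any (P, R)", {
  img <- matrix(55, 8, 8)
  expect_true(all(circular_lbp(img, 8, 1)$labels == 255))
  expect_true(all(circular_lbp(img, 8, 2)$labels == 255))
  expect_true(all(circular_lbp(img, 16, 2)$labels == 2^16 - 1))
})

test_that("nearest-integer (8,1) sampling reproduces the basic operator", {
  set.seed(11)
  img <- matrix(sample(0:255, 49, replace = TRUE), 7, 7)
  expect_equal(circular_lbp(img, 8, 1, interpolate = FALSE)$labels,
               basic_lbp(img)$labels)
})

test_that("labels are invariant to a global intensity offset", {
  set.seed(3)
  img <- matrix(sample(0:200, 64, replace = TRUE), 8, 8)
  for (shift in c(7, 55)) {
    expect_equal(circular_lbp(img + shift, 8, 2)$labels,
                 circular_lbp(img, 8, 2)$labels)
    expect_equal(basic_lbp(img + shift)$labels, basic_lbp(img)$labels)
  }
})

test_that("uniformity test counts circular transitions", {
  expect_true(is_uniform("00000000"))
  expect_true(is_uniform("11100001"))
  expect_true(is_uniform("00111000"))
  expect_false(is_uniform("01010101"))  # 8 transitions
  expect_false(is_uniform("00100100"))
  # agree with the enumeration oracle over all 8-bit patterns
  raw <- 0:255
  got <- vapply(raw, function(v)
    is_uniform(as.integer(intToBits(v))[1:8]), logical(1))
  want <- vapply(raw, function(v) oracle_transitions(v, 8) <= 2, logical(1))
  expect_equal(got, want)
})

test_that("u2 mapping bin counts match brute-force enumeration", {
  for (P in c(4, 8, 16)) {
    map <- u2_table(P)
    expect_equal(attr(map, "n_bins"), oracle_uniform_count(P) + 1L,
                 label = paste("P =", P))
  }
  expect_equal(attr(u2_table(8), "n_bins"), 59L)
  expect_equal(attr(u2_table(4), "n_bins"), 15L)
})

test_that("u2 mapping is total and surjective onto the bin range", {
  map <- u2_table(8)
  nb <- attr(map, "n_bins")
  expect_length(map, 256L)
  expect_setequal(unique(map), 0:(nb - 1))
  # uniform patterns get distinct bins; non-uniform share the last
  uni <- vapply(0:255, function(v) oracle_transitions(v, 8) <= 2, logical(1))
  expect_equal(length(unique(map[uni])), sum(uni))
  expect_true(all(map[!uni] == nb - 1L))
})

test_that("label histograms conserve pixel counts", {
  patch <- matrix(c(3, 3, 5, 7), 2, 2, byrow = TRUE)
  h <- label_histogram(patch, n_labels = 8)
  expect_equal(h, c(0, 0, 0, 2, 0, 1, 0, 1))

  set.seed(5)
  lm <- circular_lbp(matrix(sample(0:255, 400, replace = TRUE), 20, 20), 8, 2)
  expect_equal(sum(label_histogram(lm)), length(lm$labels))
  h2 <- label_histogram(lm, region = c(2, 7, 3, 9))
  expect_equal(sum(h2), 6 * 7)
  expect_error(label_histogram(lm, region = c(5, 4, 1, 2)), "region")
})

test_that("constant label maps put all mass in one bin", {
  lm <- matrix(4L, 6, 6)
  h <- label_histogram(lm, n_labels = 10)
  expect_equal(h[5], 36L)
  expect_equal(sum(h), 36L)
})

test_that("region grids tile exactly with near-equal cells", {
  g <- partition_grid(150, 110, 7, 6)
  expect_equal(g$m, 42L)
  widths <- g$regions$col2 - g$regions$col1 + 1
  heights <- g$regions$row2 - g$regions$row1 + 1
  expect_true(all(widths %in% c(18, 19)))
  expect_true(all(heights %in% c(21, 22)))

  g2 <- partition_grid(100, 100, 2, 2)
  expect_equal(g2$m, 4L)
  expect_true(all(g2$regions$col2 - g2$regions$col1 + 1 == 50))

  # property sweep: exact tiling for assorted shapes
  set.seed(9)
  for (i in 1:20) {
    h <- sample(5:60, 1); w <- sample(5:60, 1)
    r <- sample(seq_len(h), 1); cc <- sample(seq_len(w), 1)
    g3 <- partition_grid(h, w, r, cc)
    # row extents of the first grid column tile the height
    first_col <- g3$regions[g3$regions$col1 == 1, ]
    expect_equal(sum(first_col$row2 - first_col$row1 + 1), h)
    first_row <- g3$regions[g3$regions$row1 == 1, ]
    expect_equal(sum(first_row$col2 - first_row$col1 + 1), w)
    # no overlap/gap: every cell pixel covered exactly once
    cover <- matrix(0L, h, w)
    for (j in seq_len(g3$m)) {
      rr <- g3$regions[j, ]
      cover[rr$row1:rr$row2, rr$col1:rr$col2] <-
        cover[rr$row1:rr$row2, rr$col1:rr$col2] + 1L
    }
    expect_true(all(cover == 1L))
  }
  expect_error(partition_grid(10, 10, 0, 2), "at least one")
})

test_that("spatially enhanced histograms have the documented layout", {
  set.seed(13)
  img <- matrix(sample(0:255, 110 * 150, replace = TRUE), 150, 110)
  f <- lbp_features(img)
  expect_length(f, 2478L)
  expect_equal(sum(f), 146 * 106)        # conservation over the labeled area

  cimg <- matrix(77, 40, 40)
  fc <- lbp_features(cimg, n_rows = 2, n_cols = 2)
  blocks <- matrix(fc, nrow = 59)
  # all-ones pattern is uniform; all mass in its bin per region
  expect_true(all(colSums(blocks > 0) == 1))
  expect_equal(unname(colSums(blocks)), rep(18 * 18, 4))

  fn <- lbp_features(img, normalize = TRUE)
  expect_equal(sum(fn), 42)              # each region block sums to 1
})

test_that("feature matrices stack image descriptors as rows", {
  set.seed(2)
  imgs <- replicate(3, matrix(sample(0:255, 900, replace = TRUE), 30, 30),
                    simplify = FALSE)
  x <- lbp_feature_matrix(imgs, n_rows = 2, n_cols = 2)
  expect_equal(dim(x), c(3L, 59L * 4L))
  expect_equal(x[2, ], lbp_features(imgs[[2]], n_rows = 2, n_cols = 2),
               ignore_attr = TRUE)
})

test_that("eye normalization produces the standard crop geometry", {
  set.seed(21)
  src <- matrix(runif(300 * 300, 0, 255), 300, 300)
  # eyes horizontal, 55 px apart, already at the target placement:
  # output = pure crop of the source
  lx <- 120; ly <- 80
  out <- normalize_face(src, c(lx, ly, lx + 55, ly))
  expect_equal(dim(out), c(150L, 110L))
  crop <- src[(ly - 49):(ly + 100), (lx - 27):(lx + 82)]
  expect_equal(out, crop, tolerance = 1e-12)

  # eyes 110 px apart: scale factor 0.5
  out2 <- suppressWarnings(normalize_face(src, c(100, 150, 210, 150)))
  expect_equal(dim(out2), c(150L, 110L))
  # a point 20 source px right of the left eye maps 10 output px right
  expect_equal(out2[50, 28 + 10], src[150, 100 + 20], tolerance = 1e-8)

  expect_error(normalize_face(src, c(50, 50, 50, 50)), "left of")
  expect_warning(normalize_face(src, c(10, 10, 65, 10)), "replicated")
})

test_that("rotated eyes are brought level", {
  # smooth gradient so bilinear interpolation is near-exact
  src <- outer(1:400, 1:400, function(r, c) r + 0.5 * c)
  eyes <- c(150, 200 - 27.5 / sqrt(2), 150 + 55 / sqrt(2), 200 + 27.5 / sqrt(2))
  out <- normalize_face(src, eyes)
  # after normalization the eye targets read the (linear) source field at
  # the exact eye centres: f(r, c) = r + 0.5 c
  expect_equal(out[50, 28], eyes[2] + 0.5 * eyes[1], tolerance = 1e-6)
  expect_equal(out[50, 83], eyes[4] + 0.5 * eyes[3], tolerance = 1e-6)
})
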