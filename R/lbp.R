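#' Basic 3x3 local binary pattern labels
#'
#' Labels every interior pixel of a grayscale image by thresholding its eight
#' 3x3 neighbours at the centre intensity (neighbour >= centre gives bit 1)
#' and reading the bits as an 8-bit integer. Bit p is the p-th neighbour
#' starting directly above the centre and proceeding counter-clockwise; p = 0
#' is the least significant bit. This convention is shared with
#' [circular_lbp()] so the two operators agree at (P, R) = (8, 1) when
#' sampling positions are rounded to the pixel grid.
#'
#' @param img numeric matrix of intensities (rows = image rows); at least 3x3.
#' @return An object of class `lbp_labels`: a list with `labels` (integer
#'   matrix over the valid interior, i.e. excluding a 1-pixel border),
#'   `n_labels` (256), `P`, `R`, and `border` (1).
#' @seealso [circular_lbp()], [lbp_features()]
#' @examples
#' img <- matrix(sample(0:255, 25, replace = TRUE), 5, 5)
#' basic_lbp(img)$labels
#' @export
basic_lbp <- function(img) {
  img <- check_gray_image(img, min_dim = 3L)
  h <- nrow(img); w <- ncol(img)
  rows <- 2:(h - 1); cols <- 2:(w - 1)
  centre <- img[rows, cols, drop = FALSE]
  # neighbour offsets (drow, dcol): start "up", counter-clockwise
  off <- list(c(-1, 0), c(-1, -1), c(0, -1), c(1, -1),
              c(1, 0), c(1, 1), c(0, 1), c(-1, 1))
  lab <- matrix(0, length(rows), length(cols))
  for (p in 0:7) {
    o <- off[[p + 1]]
    nb <- img[rows + o[1], cols + o[2], drop = FALSE]
    lab <- lab + (nb >= centre) * 2^p
  }
  new_lbp_labels(lab, n_labels = 256L, P = 8L, R = 1, border = 1L)
}

#' Circular (P, R) local binary pattern labels
#'
#' Extended LBP operator over a circle of `P` equally spaced sampling points
#' at radius `R`. Sampling point p sits at offset
#' (-R cos(2 pi p / P), -R sin(2 pi p / P)) in (row, column) terms, i.e.
#' p = 0 is directly above the centre and the points proceed
#' counter-clockwise on screen; off-grid positions are bilinearly
#' interpolated. Neighbour >= centre gives bit 1 and bit p has weight 2^p.
#' Labels are raw (`0 .. 2^P - 1`); apply [u2_table()] for the uniform
#' mapping. Only pixels whose full circular neighbourhood fits are labeled,
#' so a border of `ceiling(R)` pixels is excluded.
#'
#' @param img numeric intensity matrix.
#' @param P number of sampling points (>= 4).
#' @param R circle radius in pixels (> 0).
#' @param interpolate bilinear interpolation of off-grid sampling points
#'   (default); `FALSE` rounds sampling offsets to the nearest pixel.
#' @return An object of class `lbp_labels` (see [basic_lbp()]); `border` is
#'   `ceiling(R)`.
#' @export
circular_lbp <- function(img, P = 8L, R = 2, interpolate = TRUE) {
  img <- check_gray_image(img, min_dim = 1L)
  if (P < 4) stop_invalid("P must be at least 4")
  if (R <= 0) stop_invalid("R must be positive")
  b <- as.integer(ceiling(R))
  h <- nrow(img); w <- ncol(img)
  if (h - 2 * b < 1 || w - 2 * b < 1)
    stop_invalid("image too small: no pixel has a complete (P = ", P,
                 ", R = ", R, ") neighbourhood")
  rows <- (b + 1):(h - b); cols <- (b + 1):(w - b)
  centre <- img[rows, cols, drop = FALSE]
  lab <- matrix(0, length(rows), length(cols))
  # comparison tolerance: bilinear weights introduce O(eps) noise on exact ties
  tol <- 1e-8 * max(1, max(abs(img)))
  for (p in 0:(P - 1)) {
    th <- 2 * pi * p / P
    dy <- -R * cos(th); dx <- -R * sin(th)
    if (!interpolate) { dy <- round(dy); dx <- round(dx) }
    y0 <- floor(dy); x0 <- floor(dx)
    fy <- dy - y0; fx <- dx - x0
    nb <- (1 - fy) * (1 - fx) * img[rows + y0, cols + x0, drop = FALSE]
    if (fx > 0) nb <- nb + (1 - fy) * fx * img[rows + y0, cols + x0 + 1, drop = FALSE]
    if (fy > 0) nb <- nb + fy * (1 - fx) * img[rows + y0 + 1, cols + x0, drop = FALSE]
    if (fy > 0 && fx > 0) nb <- nb + fy * fx * img[rows + y0 + 1, cols + x0 + 1, drop = FALSE]
    lab <- lab + (nb >= centre - tol) * 2^p
  }
  new_lbp_labels(lab, n_labels = as.integer(2^P), P = as.integer(P), R = R,
                 border = b)
}

new_lbp_labels <- function(labels, n_labels, P, R, border) {
  structure(list(labels = labels, n_labels = n_labels, P = P, R = R,
                 border = border),
            class = "lbp_labels")
}

#' @export
print.lbp_labels <- function(x, ...) {
  cat(sprintf("LBP label map: %d x %d valid pixels, (P, R) = (%d, %g), %d labels\n",
              nrow(x$labels), ncol(x$labels), x$P, x$R, x$n_labels))
  invisible(x)
}

#' Is a circular bit pattern uniform?
#'
#' A pattern is uniform (u2) when, read as a circular bit string, it contains
#' at most one 0-1 and one 1-0 transition (i.e. at most two bitwise changes
#' around the circle).
#'
#' @param pattern either a character string of `"0"`/`"1"` (e.g. `"11100001"`)
#'   or an integer/logical bit vector; length = P.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_uniform("00000000")  # TRUE
#' is_uniform("11100001")  # TRUE
#' is_uniform("01010101")  # FALSE
#' @export
is_uniform <- function(pattern) {
  bits <- as_bits(pattern)
  circular_transitions(bits) <= 2L
}

as_bits <- function(pattern) {
  if (is.character(pattern)) {
    stopifnot(length(pattern) == 1L)
    bits <- as.integer(strsplit(pattern, "")[[1]])
  } else bits <- as.integer(pattern)
  if (any(is.na(bits)) || any(!bits %in% c(0L, 1L)))
    stop_invalid("pattern must consist of 0s and 1s")
  bits
}

circular_transitions <- function(bits) {
  sum(bits != bits[c(seq_along(bits)[-1], 1L)])
}

#' Uniform-pattern (u2) label mapping
#'
#' Maps each raw P-bit LBP label to a histogram bin: every uniform pattern
#' (at most two circular bit transitions) gets its own bin, in increasing
#' raw-label order, and all non-uniform patterns share the final bin. For
#' P = 8 this yields the familiar 59-bin operator.
#'
#' @param P number of sampling points (>= 4).
#' @return Integer vector of length `2^P`; entry `i` is the 0-based bin of
#'   raw label `i - 1`. Attribute `n_bins` holds the bin count
#'   (number of uniform patterns + 1).
#' @examples
#' attr(u2_table(8), "n_bins")  # 59
#' @export
u2_table <- function(P) {
  P <- as.integer(P)
  if (P < 4) stop_invalid("P must be at least 4")
  raw <- 0:(2^P - 1)
  # bit p of each raw label
  bits <- vapply(0:(P - 1), function(p) bitwAnd(raw, bitwShiftL(1L, p)) > 0L,
                 logical(length(raw)))
  trans <- rowSums(bits != bits[, c(2:P, 1L), drop = FALSE])
  uniform <- trans <= 2L
  map <- integer(length(raw))
  map[uniform] <- seq_len(sum(uniform)) - 1L
  map[!uniform] <- sum(uniform)             # shared trailing bin
  attr(map, "n_bins") <- sum(uniform) + 1L
  map
}

#' Histogram of LBP labels over a region
#'
#' Counts label occurrences within a rectangular region of a label map
#' (whole map by default). The histogram has one bin per possible label and
#' sums exactly to the region's pixel count.
#'
#' @param lm an `lbp_labels` object, or a plain integer matrix of labels
#'   (then supply `n_labels`).
#' @param region optional `c(row1, row2, col1, col2)` extent, 1-based
#'   inclusive, in label-map coordinates.
#' @param n_labels number of distinct labels when `lm` is a bare matrix.
#' @return Integer vector of `n_labels` counts (bin i counts label i - 1).
#' @export
label_histogram <- function(lm, region = NULL, n_labels = NULL) {
  if (inherits(lm, "lbp_labels")) {
    labels <- lm$labels
    if (is.null(n_labels)) n_labels <- lm$n_labels
  } else {
    labels <- lm
    if (is.null(n_labels)) stop_invalid("n_labels required for a bare label matrix")
  }
  if (!is.null(region)) {
    stopifnot(length(region) == 4L)
    if (region[1] > region[2] || region[3] > region[4] ||
        region[1] < 1 || region[2] > nrow(labels) ||
        region[3] < 1 || region[4] > ncol(labels))
      stop_invalid("empty or out-of-range region")
    labels <- labels[region[1]:region[2], region[3]:region[4], drop = FALSE]
  }
  if (length(labels) == 0L) stop_invalid("empty region")
  tabulate(as.integer(labels) + 1L, nbins = n_labels)
}

#' Partition an area into a near-equal grid of regions
#'
#' Tiles a `height` x `width` area into `n_rows` x `n_cols` rectangular
#' regions whose widths (and heights) differ by at most one pixel, with no
#' overlap and no gap; the remainder pixels go to the trailing regions.
#'
#' @param height,width area extent in pixels.
#' @param n_rows,n_cols grid shape (>= 1, each no larger than the extent).
#' @return An object of class `region_grid`: list with `n_rows`, `n_cols`,
#'   `m` (= n_rows * n_cols) and `regions`, a data frame of row-major region
#'   extents (`row1`, `row2`, `col1`, `col2`).
#' @examples
#' partition_grid(150, 110, 7, 6)$m  # 42 regions
#' @export
partition_grid <- function(height, width, n_rows, n_cols) {
  if (n_rows < 1 || n_cols < 1) stop_invalid("grid must have at least one row and column")
  if (n_rows > height || n_cols > width)
    stop_invalid("more grid cells than pixels along an axis")
  rb <- split_extent(height, n_rows)
  cb <- split_extent(width, n_cols)
  regions <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  regions <- data.frame(row1 = rb$from[regions$row], row2 = rb$to[regions$row],
                        col1 = cb$from[regions$col], col2 = cb$to[regions$col])
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 m = as.integer(n_rows * n_cols), height = height, width = width,
                 regions = regions),
            class = "region_grid")
}

split_extent <- function(n, k) {
  base <- n %/% k; rem <- n %% k
  sizes <- rep(base, k)
  if (rem > 0) sizes[(k - rem + 1):k] <- base + 1   # remainder to trailing regions
  to <- cumsum(sizes)
  list(from = to - sizes + 1L, to = to)
}

#' @export
print.region_grid <- function(x, ...) {
  cat(sprintf("Region grid: %d x %d = %d regions over %g x %g pixels\n",
              x$n_rows, x$n_cols, x$m, x$height, x$width))
  invisible(x)
}

#' Spatially enhanced uniform-LBP histogram features
#'
#' The full texture descriptor for one grayscale face image: label the image
#' with the circular LBP operator, optionally collapse labels through the u2
#' uniform mapping, partition the labeled area (the image minus a
#' `ceiling(R)` border) into an `n_rows` x `n_cols` grid, histogram each
#' region and concatenate the histograms row-major by region. With the
#' default 59-bin (8, 2) operator and 6 x 7 grid on a 110 x 150 image this
#' gives the 2478-dimensional descriptor (59 bins x 42 regions).
#'
#' @param img numeric intensity matrix (height x width).
#' @param P,R circular LBP parameters; see [circular_lbp()].
#' @param uniform apply the u2 uniform mapping (default `TRUE`).
#' @param n_rows,n_cols region grid shape (default 7 x 6).
#' @param normalize divide each region histogram by its pixel count
#'   (default `FALSE`: raw counts).
#' @return Numeric vector of length `m * n` (regions x bins) with attributes
#'   `P`, `R`, `uniform`, `n_bins`, `grid` = c(n_rows, n_cols).
#' @examples
#' img <- matrix(runif(110 * 150, 0, 255), nrow = 150, ncol = 110)
#' length(lbp_features(img))  # 2478
#' @export
lbp_features <- function(img, P = 8L, R = 2, uniform = TRUE,
                         n_rows = 7L, n_cols = 6L, normalize = FALSE) {
  lm <- circular_lbp(img, P = P, R = R)
  if (uniform) {
    map <- u2_table(P)
    lm$labels[] <- map[as.integer(lm$labels) + 1L]
    lm$n_labels <- attr(map, "n_bins")
  }
  grid <- partition_grid(nrow(lm$labels), ncol(lm$labels), n_rows, n_cols)
  blocks <- lapply(seq_len(grid$m), function(i) {
    r <- grid$regions[i, ]
    h <- label_histogram(lm, region = c(r$row1, r$row2, r$col1, r$col2))
    if (normalize) h <- h / sum(h)
    h
  })
  out <- unlist(blocks, use.names = FALSE)
  attributes(out) <- c(attributes(out),
                       list(P = as.integer(P), R = R, uniform = uniform,
                            n_bins = lm$n_labels,
                            grid = c(n_rows = as.integer(n_rows),
                                     n_cols = as.integer(n_cols))))
  out
}

#' LBP feature matrix for a list of images
#'
#' Applies [lbp_features()] to every image and stacks the descriptors as the
#' rows of a matrix (samples x features).
#'
#' @param images list of intensity matrices (all the same size).
#' @param ... passed to [lbp_features()].
#' @return Numeric matrix, one row per image.
#' @export
lbp_feature_matrix <- function(images, ...) {
  stopifnot(length(images) >= 1L)
  feats <- lapply(images, lbp_features, ...)
  len <- lengths(feats)
  if (length(unique(len)) != 1L)
    stop_invalid("images produced descriptors of different lengths")
  out <- do.call(rbind, feats)
  meta <- attributes(feats[[1]])
  for (a in c("P", "R", "uniform", "n_bins", "grid"))
    attr(out, a) <- meta[[a]]
  out
}

#' Eye-based geometric normalization of a face image
#'
#' Applies the similarity transform (rotation to horizontal eyes plus uniform
#' scaling) that brings the inter-ocular distance to `eye_dist` pixels, then
#' crops a `width` x `height` window with the eye centres placed
#' symmetrically about the vertical midline at one third of the output
#' height. The default geometry (55 px eye distance, 110 x 150 crop) follows
#' the convention that a face is roughly two eye distances wide and three
#' tall. Bilinear resampling; samples falling outside the source are filled
#' by edge replication with a warning.
#'
#' @param img numeric intensity matrix.
#' @param eyes list or vector giving eye centres in (x = column, y = row)
#'   pixel coordinates: either `list(left = c(x, y), right = c(x, y))` or a
#'   numeric vector `c(lx, ly, rx, ry)`. The left eye must have the smaller
#'   x (image left).
#' @param eye_dist target inter-ocular distance in pixels.
#' @param width,height output crop size in pixels.
#' @return Intensity matrix of size `height` x `width`.
#' @export
normalize_face <- function(img, eyes, eye_dist = 55, width = 110L, height = 150L) {
  img <- check_gray_image(img, min_dim = 2L)
  e <- parse_eyes(eyes, nrow(img), ncol(img))
  d <- sqrt(sum((e$right - e$left)^2))
  if (d <= .Machine$double.eps) stop_invalid("eye centres coincide")
  s <- eye_dist / d
  ang <- atan2(e$right[2] - e$left[2], e$right[1] - e$left[1])
  # output-plane eye targets (x, y): symmetric about the midline, row = height/3
  midx <- (1 + width) / 2
  eyeL_out <- c(midx - eye_dist / 2, height / 3)
  # inverse map: output point -> source point
  ca <- cos(ang); sa <- sin(ang)
  gx <- matrix(rep(seq_len(width), each = height), height, width)
  gy <- matrix(rep(seq_len(height), width), height, width)
  ux <- (gx - eyeL_out[1]) / s
  uy <- (gy - eyeL_out[2]) / s
  sx <- e$left[1] + ca * ux - sa * uy
  sy <- e$left[2] + sa * ux + ca * uy
  out_of_range <- sx < 1 | sx > ncol(img) | sy < 1 | sy > nrow(img)
  if (any(out_of_range))
    warning("crop exceeds source image after transform; edge pixels replicated")
  bilinear_sample(img, sy, sx)
}

parse_eyes <- function(eyes, h, w) {
  if (is.list(eyes)) {
    left <- as.numeric(eyes$left); right <- as.numeric(eyes$right)
  } else {
    eyes <- as.numeric(eyes)
    stopifnot(length(eyes) == 4L)
    left <- eyes[1:2]; right <- eyes[3:4]
  }
  if (length(left) != 2L || length(right) != 2L)
    stop_invalid("eyes must give (x, y) for left and right")
  if (any(!is.finite(c(left, right)))) stop_invalid("non-finite eye coordinates")
  if (left[1] >= right[1]) stop_invalid("left eye must be left of right eye (left.x < right.x)")
  if (left[1] < 1 || left[1] > w || right[1] < 1 || right[1] > w ||
      left[2] < 1 || left[2] > h || right[2] < 1 || right[2] > h)
    stop_invalid("eye coordinates outside the image")
  list(left = left, right = right)
}

# vectorized bilinear sampling with edge replication (sy, sx are matrices of
# fractional source coordinates)
bilinear_sample <- function(img, sy, sx) {
  h <- nrow(img); w <- ncol(img)
  sy <- pmin(pmax(sy, 1), h)
  sx <- pmin(pmax(sx, 1), w)
  y0 <- pmin(floor(sy), h - 1); x0 <- pmin(floor(sx), w - 1)
  fy <- sy - y0; fx <- sx - x0
  i00 <- cbind(as.vector(y0), as.vector(x0))
  i01 <- cbind(as.vector(y0), as.vector(x0) + 1)
  i10 <- cbind(as.vector(y0) + 1, as.vector(x0))
  i11 <- cbind(as.vector(y0) + 1, as.vector(x0) + 1)
  v <- (1 - fy) * (1 - fx) * img[i00] + (1 - fy) * fx * img[i01] +
    fy * (1 - fx) * img[i10] + fy * fx * img[i11]
  matrix(v, nrow(sy), ncol(sy))
}

check_gray_image <- function(img, min_dim = 3L) {
  if (!is.matrix(img) || !is.numeric(img))
    stop_invalid("image must be a numeric matrix")
  if (nrow(img) < min_dim || ncol(img) < min_dim)
    stop_invalid("image must be at least ", min_dim, "x", min_dim)
  if (any(!is.finite(img))) stop_invalid("image intensities must be finite")
  img
}
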