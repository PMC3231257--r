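#' Swiss-roll manifold benchmark sample
#'
#' Draws points on the classic swiss roll
#' \eqn{(t \cos t,\; h,\; t \sin t)} with \eqn{t} uniform on
#' [1.5 pi, 4.5 pi] and height \eqn{h} uniform on [0, 21]. The true unrolled
#' coordinates (arc length along the spiral, height) are returned so
#' isometry recovery can be scored exactly: with zero noise the map from
#' `manifold_coords` to `points` is an isometry.
#'
#' @param n number of points (>= 10).
#' @param noise_sd standard deviation of additive Gaussian ambient noise
#'   (default 0).
#' @param seed integer seed; the sample is deterministic given the seed.
#' @return An object of class `swiss_roll`: list with `points` (n x 3),
#'   `manifold_coords` (n x 2: arc length, height), `t`, `noise_sd`, `seed`.
#' @export
make_swiss_roll <- function(n, noise_sd = 0, seed = NULL) {
  if (n < 10) stop_invalid("n must be at least 10")
  with_seed(seed, {
    t <- runif(n, 1.5 * pi, 4.5 * pi)
    h <- runif(n, 0, 21)
    pts <- cbind(t * cos(t), h, t * sin(t))
    if (noise_sd > 0) pts <- pts + matrix(rnorm(3 * n, sd = noise_sd), n, 3)
    structure(list(points = pts,
                   manifold_coords = cbind(spiral_arclength(t), h),
                   t = t, noise_sd = noise_sd, seed = seed),
              class = "swiss_roll")
  })
}

# arc length of the spiral (t cos t, t sin t) from 0:
# integral of sqrt(1 + u^2) du = (u sqrt(1 + u^2) + asinh(u)) / 2
spiral_arclength <- function(t) {
  (t * sqrt(1 + t^2) + asinh(t)) / 2
}

#' @export
print.swiss_roll <- function(x, ...) {
  cat(sprintf("Swiss roll sample: n = %d, noise sd = %g\n",
              nrow(x$points), x$noise_sd))
  invisible(x)
}

#' Synthetic labeled face-expression image set
#'
#' Deterministic stand-in for a facial-expression database: each class is a
#' distinct procedural texture manifold and each subject contributes a fixed
#' smooth intensity field, so the set has the structure the embedding
#' methods assume — classes on distinct nonlinear image manifolds with
#' per-subject appearance variation — without any external data.
#'
#' Each image is built as
#' base intensity + separation x class texture(u) +
#' (1 - separation) x common texture(u) + subject field + pixel noise,
#' clipped to [0, 255]. The class texture is an oriented sinusoidal grating
#' (orientation and frequency indexed by the class) plus two localized
#' Gaussian blobs whose centres move smoothly with a per-image latent
#' parameter u in [0, 1], so each class traces a one-parameter nonlinear
#' manifold in image space. At `separation = 0` every class draws from the
#' same common texture distribution, so recognition falls to chance; the
#' knob is monotone.
#'
#' @param n_subjects number of subjects (>= 10 so 10-fold subject-grouped
#'   CV is possible; default 10).
#' @param images_per_cell images per (subject, class) cell (default 2).
#' @param n_classes number of expression classes (default 7).
#' @param separation class-texture weight in [0, 1] (default 1).
#' @param subject_sd amplitude of the per-subject smooth intensity field in
#'   gray levels (default 12).
#' @param noise_sd pixel noise standard deviation in gray levels (default 4).
#' @param width,height image size in pixels (default 110 x 150, the
#'   standard normalized face crop).
#' @param seed integer seed; images are byte-identical given the seed.
#' @return An object of class `expression_set`: list with `images` (list of
#'   height x width matrices in [0, 255]), `labels` (factor, class per
#'   image), `subjects` (integer per image), `latent` (u per image), and the
#'   generator parameters.
#' @export
make_expression_dataset <- function(n_subjects = 10L, images_per_cell = 2L,
                                    n_classes = 7L, separation = 1,
                                    subject_sd = 12, noise_sd = 4,
                                    width = 110L, height = 150L,
                                    seed = NULL) {
  if (n_subjects < 10) stop_invalid("n_subjects must be at least 10")
  if (images_per_cell < 1) stop_invalid("images_per_cell must be positive")
  if (separation < 0 || separation > 1)
    stop_invalid("separation must lie in [0, 1]")
  if (subject_sd < 0 || noise_sd < 0)
    stop_invalid("noise amplitudes must be nonnegative")
  with_seed(seed, {
    gx <- matrix(rep(seq_len(width), each = height), height, width) / width
    gy <- matrix(rep(seq_len(height), width), height, width) / height
    subject_fields <- lapply(seq_len(n_subjects), function(s)
      subject_sd * smooth_field(gx, gy))
    n <- n_subjects * n_classes * images_per_cell
    images <- vector("list", n)
    labels <- integer(n); subjects <- integer(n); latent <- numeric(n)
    i <- 0L
    for (s in seq_len(n_subjects)) for (cl in seq_len(n_classes)) {
      for (r in seq_len(images_per_cell)) {
        i <- i + 1L
        u <- runif(1)
        tex <- separation * class_texture(cl, u, gx, gy) +
          (1 - separation) * class_texture(0L, u, gx, gy)
        img <- 128 + tex + subject_fields[[s]] +
          matrix(rnorm(height * width, sd = noise_sd), height, width)
        images[[i]] <- pmin(pmax(img, 0), 255)
        labels[i] <- cl; subjects[i] <- s; latent[i] <- u
      }
    }
    structure(list(images = images,
                   labels = factor(paste0("class", labels)),
                   subjects = subjects, latent = latent,
                   params = list(n_subjects = n_subjects,
                                 images_per_cell = images_per_cell,
                                 n_classes = n_classes,
                                 separation = separation,
                                 subject_sd = subject_sd,
                                 noise_sd = noise_sd,
                                 width = width, height = height,
                                 seed = seed)),
              class = "expression_set")
  })
}

# oriented grating + moving blobs; class 0 is the "common" texture shared by
# all classes at separation 0
class_texture <- function(class_id, u, gx, gy) {
  th <- pi * class_id / 7.3          # class-specific orientation
  freq <- 9 + 2.6 * class_id         # class-specific spatial frequency
  phase <- 2 * pi * u
  cx <- cos(th) * gx + sin(th) * gy
  cyq <- -sin(th) * gx + cos(th) * gy
  g <- 40 * sin(2 * pi * freq * cx + phase) +
    14 * sin(2 * pi * (freq / 2) * cyq + 0.5 * phase)
  # two blobs whose centres trace a class-specific curve in u
  b1x <- 0.3 + 0.4 * u; b1y <- 0.3 + 0.35 * sin(pi * u + th)
  b2x <- 0.7 - 0.4 * u; b2y <- 0.65 + 0.25 * cos(pi * u + th)
  g <- g + 35 * exp(-((gx - b1x)^2 + (gy - b1y)^2) / (2 * 0.06^2 * (1 + class_id))) -
    35 * exp(-((gx - b2x)^2 + (gy - b2y)^2) / (2 * 0.08^2))
  g
}

# smooth random field: a few low-frequency sinusoids with random phase
smooth_field <- function(gx, gy) {
  f <- matrix(0, nrow(gx), ncol(gx))
  for (j in 1:3) {
    fx <- runif(1, 0.5, 2); fy <- runif(1, 0.5, 2)
    ph <- runif(2, 0, 2 * pi)
    f <- f + sin(2 * pi * fx * gx + ph[1]) * cos(2 * pi * fy * gy + ph[2])
  }
  f / sqrt(3)
}

#' @export
print.expression_set <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("Synthetic expression set: %d images (%d subjects x %d",
                     " classes x %d), %d x %d px\n"),
              length(x$images), p$n_subjects, p$n_classes,
              p$images_per_cell, p$height, p$width))
  cat(sprintf("  separation %g, subject sd %g, noise sd %g\n",
              p$separation, p$subject_sd, p$noise_sd))
  invisible(x)
}

#' Write a synthetic expression set to disk
#'
#' Writes each image as a PNG plus a manifest CSV in the dataset-manifest
#' dialect (`path,label,subject`), so the set round-trips through
#' [read_manifest()] and [load_dataset()].
#'
#' @param set an `expression_set`.
#' @param dir output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_expression_set <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- sprintf("img%04d.png", seq_along(set$images))
  for (i in seq_along(set$images))
    write_gray_png(set$images[[i]], file.path(dir, paths[i]))
  manifest <- data.frame(path = paths, label = set$labels,
                         subject = set$subjects)
  mp <- file.path(dir, "manifest.csv")
  write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}
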