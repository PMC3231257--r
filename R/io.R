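#' Read a grayscale image
#'
#' Reads PNG, TIFF or PGM (P2 ASCII / P5 binary) images as an intensity
#' matrix on the 0-255 scale. Colour images are converted to grayscale by
#' averaging the channels, with a warning.
#'
#' @param path file path; format chosen by extension (`.png`, `.tif`/`.tiff`,
#'   `.pgm`).
#' @return Numeric matrix of intensities in [0, 255].
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop_invalid("no such image: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    to_gray(a) * 255
  } else if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path)
    to_gray(a) * 255
  } else if (ext == "pgm") {
    read_pgm(path)
  } else stop_invalid("unsupported image format: .", ext)
}

to_gray <- function(a) {
  if (length(dim(a)) == 3L) {
    nc <- dim(a)[3]
    keep <- min(nc, 3L)  # drop alpha
    warning("colour image converted to grayscale by channel average")
    apply(a[, , seq_len(keep), drop = FALSE], c(1, 2), mean)
  } else a
}

# PGM P2 (ASCII) and P5 (8-bit binary); small-format reader, no package in
# the dependency set handles PGM.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5")) stop_invalid("not a PGM (P2/P5) file: ", path)
  toks <- character(0)
  buf <- character(0)
  # read header tokens (width, height, maxval), skipping comments
  while (length(toks) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (length(ch) == 0L || ch == "") stop_invalid("truncated PGM header")
    if (ch == "#") { # comment to end of line
      repeat {
        c2 <- rawToChar(readBin(con, "raw", 1L))
        if (c2 %in% c("\n", "\r", "")) break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) { toks <- c(toks, paste(buf, collapse = "")); buf <- character(0) }
    } else buf <- c(buf, ch)
  }
  dims <- as.integer(toks)
  w <- dims[1]; h <- dims[2]; maxval <- dims[3]
  n <- w * h
  if (magic == "P5") {
    if (maxval > 255) stop_invalid("16-bit PGM not supported")
    v <- as.integer(readBin(con, "raw", n))
  } else {
    v <- scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(v) != n) stop_invalid("truncated PGM pixel data")
  matrix(v, nrow = h, ncol = w, byrow = TRUE) * (255 / maxval)
}

#' Write a grayscale image as PNG
#'
#' @param img intensity matrix on the 0-255 scale (clipped).
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  img <- pmin(pmax(img, 0), 255) / 255
  png::writePNG(img, path)
  invisible(path)
}

#' Read a dataset manifest
#'
#' The manifest is a CSV with header
#' `path,label,subject,eye_lx,eye_ly,eye_rx,eye_ry`; the four eye columns are
#' optional (absent means the images are already cropped and aligned).
#' Relative image paths are resolved against the manifest's directory.
#'
#' @param path manifest CSV path.
#' @return Data frame with `path`, `label` (factor), `subject` and, when
#'   present, the eye-coordinate columns.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "label", "subject")
  if (!all(need %in% names(m)))
    stop_invalid("manifest must have columns: ", paste(need, collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m$label <- factor(m$label)
  m
}

#' Load a manifest's images as an LBP feature matrix
#'
#' Reads every image in a manifest, applies eye-based normalization when the
#' manifest carries eye coordinates, and extracts spatially enhanced LBP
#' histograms.
#'
#' @param manifest data frame from [read_manifest()] (or a manifest path).
#' @param ... passed to [lbp_features()].
#' @return List with `x` (feature matrix), `labels` (factor) and `subjects`.
#' @export
load_dataset <- function(manifest, ...) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  eye_cols <- c("eye_lx", "eye_ly", "eye_rx", "eye_ry")
  has_eyes <- all(eye_cols %in% names(manifest))
  images <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_gray_image(manifest$path[i])
    if (has_eyes && all(is.finite(as.numeric(manifest[i, eye_cols]))))
      img <- normalize_face(img, as.numeric(manifest[i, eye_cols]))
    img
  })
  list(x = lbp_feature_matrix(images, ...),
       labels = factor(manifest$label), subjects = manifest$subject)
}

#' Write / read a feature matrix as delimited text
#'
#' Features are written as a tab-separated matrix (rows = samples) with a
#' JSON sidecar (`<path>.json`) recording descriptor metadata.
#'
#' @param x numeric matrix (typically from [lbp_feature_matrix()]).
#' @param path output TSV path.
#' @param meta optional named list stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_features <- function(x, path, meta = NULL) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  side <- attributes(x)
  side$dim <- NULL; side$dimnames <- NULL
  side <- c(side, meta)
  if (length(side))
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t"))
}

#' Write / read a dissimilarity matrix as delimited text
#'
#' The first line is a header tag `# kind=<kernel_euclidean|discriminant|geodesic>`.
#'
#' @param m symmetric nonnegative matrix.
#' @param path output path.
#' @param kind dissimilarity kind tag.
#' @return `path` invisibly (write); the matrix with attribute `kind` (read).
#' @export
write_dissimilarity <- function(m, path,
                                kind = c("kernel_euclidean", "discriminant", "geodesic")) {
  kind <- match.arg(kind)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# kind=", kind), con)
  utils::write.table(m, con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_dissimilarity
#' @export
read_dissimilarity <- function(path) {
  first <- readLines(path, n = 1L)
  kind <- sub("^# kind=", "", first)
  m <- as.matrix(utils::read.table(path, sep = "\t", skip = 1L))
  dimnames(m) <- NULL
  attr(m, "kind") <- kind
  m
}
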