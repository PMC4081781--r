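#' @useDynLib vowrhog, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Coordinate convention used throughout the package: images are numeric
# matrices indexed [row, col], 1-based in R, with gray values in [0, 255].
# The +x axis is increasing column, +y is increasing row; angles are measured
# counter-clockwise from +x and reduced to [0, 2*pi).

#' Validate and coerce a grayscale image
#'
#' A gray image is a plain numeric matrix with finite values nominally in
#' \[0, 255\]. Both dimensions must be at least 8 pixels.
#'
#' @param pixels Numeric matrix of gray values.
#' @return The validated matrix (invisibly unchanged).
#' @export
as_gray_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("gray image must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 8L || ncol(pixels) < 8L)
    stop("gray image must be at least 8x8 pixels", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("gray image contains non-finite values", call. = FALSE)
  storage.mode(pixels) <- "double"
  pixels
}

# Internal: looser check for small working matrices (oracles, kernels).
check_image_matrix <- function(img, min_side = 1L) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("expected a numeric matrix", call. = FALSE)
  if (nrow(img) < min_side || ncol(img) < min_side)
    stop(sprintf("image must be at least %dx%d", min_side, min_side),
         call. = FALSE)
  if (!all(is.finite(img)))
    stop("image contains non-finite values", call. = FALSE)
  img
}

#' Read a grayscale raster image
#'
#' Reads PNG or PGM (P2/P5) files into a gray matrix in \[0, 255\]. RGB(A)
#' input is converted to luminance with the Rec. 601 weights
#' 0.299 R + 0.587 G + 0.114 B.
#'
#' @param path Path to a `.png`, `.pgm` file.
#' @return Numeric matrix of gray values in \[0, 255\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3L) {
      ch <- function(k) matrix(arr[, , k], dim(arr)[1L], dim(arr)[2L])
      g <- if (dim(arr)[3L] >= 3L)
        0.299 * ch(1L) + 0.587 * ch(2L) + 0.114 * ch(3L)
      else ch(1L)
    } else {
      g <- arr
    }
    img <- g * 255
  } else if (ext == "pgm") {
    img <- read_pgm(path)
  } else {
    stop("unsupported raster format: .", ext, " (use png or pgm)",
         call. = FALSE)
  }
  if (length(img) == 0L) stop("zero-size image: ", path, call. = FALSE)
  storage.mode(img) <- "double"
  img
}

#' Write a grayscale raster image
#'
#' Values are clipped to \[0, 255\] and quantized to 8 bits on write, so
#' `read_image(write_image(img))` is the identity on 8-bit content.
#'
#' @param img Gray matrix in \[0, 255\].
#' @param path Output path ending in `.png` or `.pgm`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  check_image_matrix(img)
  q <- pmin(pmax(round(img), 0), 255)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(q / 255, path)
  } else if (ext == "pgm") {
    write_pgm(q, path)
  } else {
    stop("unsupported output format: .", ext, call. = FALSE)
  }
  invisible(path)
}

# PGM (portable graymap) reader: binary P5 and ASCII P2, maxval <= 255.
# No reader for this format exists among the package's dependencies.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P5", "P2")) stop("not a PGM file: ", path, call. = FALSE)
  # header tokens: width, height, maxval; '#' starts a comment to end of line
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || ch == "") stop("truncated PGM header")
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (ch %in% c("\n", "\r") || ch == "") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok) else next
      }
      tok <- paste0(tok, ch)
    }
  }
  w <- as.integer(read_token())
  h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (is.na(w) || is.na(h) || w < 1L || h < 1L)
    stop("zero-size or malformed PGM image", call. = FALSE)
  if (maxval > 255L) stop("16-bit PGM not supported", call. = FALSE)
  if (magic == "P5") {
    raw <- readBin(con, "integer", n = w * h, size = 1L, signed = FALSE)
  } else {
    txt <- readChar(con, file.size(path), useBytes = TRUE)
    raw <- as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1L]])
    if (length(raw) < w * h) stop("truncated PGM data", call. = FALSE)
    raw <- raw[seq_len(w * h)]
  }
  # PGM stores rows top-to-bottom, row-major
  matrix(as.double(raw), nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(img, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(img), nrow(img)), con,
            eos = NULL)
  writeBin(as.integer(t(img)), con, size = 1L)
  invisible(path)
}

#' Partition an image into non-overlapping square blocks
#'
#' Blocks of side `b` tile the largest `b`-multiple sub-rectangle anchored at
#' the top-left; trailing remainder rows/columns are dropped so every block
#' has full size and per-block histograms stay comparable.
#'
#' @param img Gray matrix.
#' @param b Block side in pixels (>= 4, <= min dimension).
#' @return A list with `block_size`, `n_rows`, `n_cols`, and `blocks`: a
#'   row-major list of `list(row, col, pixels)` entries where `row`/`col` are
#'   0-based block indices.
#' @export
partition_blocks <- function(img, b) {
  check_image_matrix(img)
  b <- as.integer(b)
  if (b < 4L) stop("block size must be >= 4", call. = FALSE)
  if (b > min(dim(img)))
    stop("block size exceeds image dimensions", call. = FALSE)
  nbr <- nrow(img) %/% b
  nbc <- ncol(img) %/% b
  blocks <- vector("list", nbr * nbc)
  k <- 1L
  for (i in seq_len(nbr)) {
    for (j in seq_len(nbc)) {
      rows <- ((i - 1L) * b + 1L):(i * b)
      cols <- ((j - 1L) * b + 1L):(j * b)
      blocks[[k]] <- list(row = i - 1L, col = j - 1L,
                          pixels = img[rows, cols, drop = FALSE])
      k <- k + 1L
    }
  }
  list(block_size = b, n_rows = nbr, n_cols = nbc, blocks = blocks)
}

# Clip to the printable gray range.
clip255 <- function(x) pmin(pmax(x, 0), 255)

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Bilinear sample of img at (possibly fractional) row/col coordinates.
# Coordinates are 1-based; callers guarantee they stay inside
# [1, nrow] x [1, ncol]. Vectorized over coordinate vectors.
bilinear_sample <- function(img, row, col) {
  h <- nrow(img); w <- ncol(img)
  r0 <- floor(row); c0 <- floor(col)
  r0 <- pmin(pmax(r0, 1), h - 1L)
  c0 <- pmin(pmax(c0, 1), w - 1L)
  fr <- row - r0; fc <- col - c0
  i00 <- (c0 - 1) * h + r0
  v00 <- img[i00];       v10 <- img[i00 + 1]
  v01 <- img[i00 + h];   v11 <- img[i00 + h + 1]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}
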