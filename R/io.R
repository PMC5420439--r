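#' Construct a fundus image object
#'
#' Thin container around an `H x W x 3` numeric array with values in
#' `[0, 1]`. All pipeline entry points accept this object.
#'
#' @param pixels numeric array of dimension `H x W x 3`, values in `[0, 1]`.
#' @param source_path optional path the raster was read from.
#' @return an object of class `fundus_image` with fields `pixels`, `height`,
#'   `width`, `source_path`.
#' @export
fundus_image <- function(pixels, source_path = NA_character_) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L)
    stop("fundus_image: 'pixels' must be an H x W x 3 array, got ",
         paste(d, collapse = " x "))
  if (!all(is.finite(pixels)))
    stop("fundus_image: non-finite pixel values")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("fundus_image: pixel values must lie in [0, 1]")
  structure(
    list(pixels = pixels, height = d[1], width = d[2],
         source_path = source_path),
    class = "fundus_image")
}

#' @export
print.fundus_image <- function(x, ...) {
  cat(sprintf("<fundus_image %d x %d, range [%.3f, %.3f]>\n",
              x$height, x$width, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Load a color fundus photograph
#'
#' Reads a PNG, JPEG or (binary or ASCII) PPM raster and rescales it to
#' `[0, 1]` (8-bit inputs are divided by 255, 16-bit by 65535). Grayscale
#' and alpha-channel inputs are rejected: the pipeline requires exactly
#' three channels.
#'
#' @param path path to a `.png`, `.jpg`/`.jpeg`, or `.ppm` file.
#' @return a [fundus_image].
#' @export
load_fundus <- function(path) {
  if (!file.exists(path)) stop("load_fundus: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    ppm = read_ppm(path),
    tif = ,
    tiff = stop("load_fundus: TIFF input is not supported in this build; ",
                "convert to PNG or PPM"),
    stop("load_fundus: unsupported file extension '.", ext, "'"))
  d <- dim(px)
  nc <- if (length(d) == 3L) d[3] else 1L
  if (nc != 3L)
    stop("load_fundus: expected a 3-channel RGB image, got ", nc,
         " channel(s) in ", path)
  # readPNG/readJPEG already rescale to [0,1]; clamp away rounding fuzz
  px[px < 0] <- 0; px[px > 1] <- 1
  fundus_image(px, source_path = path)
}

# Minimal netpbm PPM reader (P3 ASCII and P6 binary, maxval <= 65535).
# Used so fixtures can be stored as plain text.
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() { # whitespace/comment-aware token scanner
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("read_ppm: truncated header")
      if (ch == "#") { repeat { c2 <- readChar(con, 1L, useBytes = TRUE)
        if (length(c2) == 0L || c2 == "\n") break } ; next }
      if (!grepl("[ \t\r\n]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || grepl("[ \t\r\n]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- tok()
  if (!magic %in% c("P3", "P6")) stop("read_ppm: not a P3/P6 PPM file")
  W <- as.integer(tok()); H <- as.integer(tok()); mx <- as.integer(tok())
  n <- 3L * W * H
  vals <- if (magic == "P6") {
    if (mx < 256) as.integer(readBin(con, "raw", n))
    else {
      raw2 <- readBin(con, "raw", 2L * n)
      hi <- as.integer(raw2[seq(1L, 2L * n, 2L)])
      lo <- as.integer(raw2[seq(2L, 2L * n, 2L)])
      hi * 256L + lo
    }
  } else {
    scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(vals) != n) stop("read_ppm: truncated pixel data")
  # PPM is row-major RGB-interleaved
  arr <- array(0, dim = c(H, W, 3L))
  m <- matrix(vals, nrow = 3L)
  for (k in 1:3) arr[, , k] <- matrix(m[k, ], nrow = H, byrow = TRUE)
  arr / mx
}

#' Write an RGB array or mask as PNG
#'
#' @param x `H x W x 3` array in `[0,1]`, an `H x W` matrix in `[0,1]`, or a
#'   logical matrix (written as 0/1).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(x, path) {
  if (is.logical(x)) x <- matrix(as.numeric(x), nrow(x), ncol(x))
  x[x < 0] <- 0; x[x > 1] <- 1
  png::writePNG(x, target = path)
  invisible(path)
}

#' Read a binary mask written by [write_image_png()]
#'
#' @param path PNG path.
#' @param threshold values strictly above this are `TRUE`.
#' @return logical matrix.
#' @export
read_mask_png <- function(path, threshold = 0.5) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  px > threshold
}
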