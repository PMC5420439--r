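#' Disc structuring element
#'
#' Discrete Euclidean disc: a pixel offset belongs to the element iff its
#' centre distance is at most `radius`.
#'
#' @param radius disc radius in pixels (>= 1).
#' @return integer matrix of `(dy, dx)` offsets.
#' @export
disc_se <- function(radius) {
  if (radius < 1) stop("disc_se: radius must be >= 1")
  r <- as.integer(ceiling(radius))
  g <- expand.grid(dy = -r:r, dx = -r:r)
  keep <- g$dy^2 + g$dx^2 <= radius^2
  out <- as.matrix(g[keep, , drop = FALSE])
  attr(out, "disc_radius") <- radius   # enables the decomposed fast path
  out
}

#' Line structuring element
#'
#' Bresenham-style digital line of `length` pixels centred on the origin at
#' angle `angle_deg` (degrees, counter-clockwise from the +x axis).
#'
#' @param length odd pixel count.
#' @param angle_deg orientation in degrees.
#' @return integer matrix of `(dy, dx)` offsets.
#' @export
line_se <- function(length, angle_deg) {
  if (length < 1) stop("line_se: length must be >= 1")
  h <- (length - 1) / 2
  t <- seq(-h, h, by = 1)
  th <- angle_deg * pi / 180
  off <- cbind(dy = round(-t * sin(th)), dx = round(t * cos(th)))
  unique(off)
}

se_matrix <- function(se) {
  se <- as.matrix(se)
  storage.mode(se) <- "integer"
  se
}

#' Grayscale erosion, dilation, opening and closing
#'
#' Flat morphology with an arbitrary structuring element (see [disc_se()],
#' [line_se()]). Out-of-bounds neighbours are ignored, so constants are
#' preserved, opening is anti-extensive and closing extensive everywhere
#' including the border.
#'
#' @param img numeric matrix.
#' @param se offset matrix from [disc_se()] or [line_se()].
#' @return numeric matrix of the same shape.
#' @export
m_erode <- function(img, se) {
  r <- attr(se, "disc_radius")
  if (!is.null(r)) cpp_erode_disc(img, r) else cpp_erode(img, se_matrix(se))
}

#' @rdname m_erode
#' @export
m_dilate <- function(img, se) {
  r <- attr(se, "disc_radius")
  if (!is.null(r)) cpp_dilate_disc(img, r) else cpp_dilate(img, se_matrix(se))
}

#' @rdname m_erode
#' @export
m_open <- function(img, se) m_dilate(m_erode(img, se), se)

#' @rdname m_erode
#' @export
m_close <- function(img, se) m_erode(m_dilate(img, se), se)

#' Median filter
#'
#' @param img numeric matrix.
#' @param k odd window side; windows are clipped at the border.
#' @return filtered matrix.
#' @export
median_filter <- function(img, k) {
  if (k < 1 || k %% 2 == 0) stop("median_filter: k must be odd and >= 1")
  cpp_median_filter(img, as.integer(k))
}

#' Morphological reconstruction by dilation
#'
#' Iterated geodesic dilation of `marker` under `mask` (8-connectivity)
#' until stability, computed with the hybrid raster/queue algorithm.
#'
#' @param marker numeric matrix, `marker <= mask` pixelwise.
#' @param mask numeric matrix.
#' @return reconstructed matrix.
#' @export
m_reconstruct <- function(marker, mask) {
  if (any(marker > mask + 1e-12))
    stop("m_reconstruct: marker must be <= mask pixelwise")
  cpp_reconstruct_dilate(pmin(marker, mask), mask)
}

#' Opening by reconstruction
#'
#' Erodes with `se` and reconstructs under the original image, preserving
#' connected structures that survive the erosion.
#'
#' @inheritParams m_erode
#' @export
m_open_reconstruct <- function(img, se) {
  m_reconstruct(m_erode(img, se), img)
}

#' Regional minima
#'
#' Connected plateaus whose neighbours are all strictly brighter, extracted
#' through the h-minima transform with an infinitesimal depth.
#'
#' @param img numeric matrix.
#' @param h depth tolerance (default effectively 0).
#' @return logical matrix.
#' @export
regional_minima <- function(img, h = 1e-7) {
  # reconstruction by erosion of (img + h) under img, via duality
  rec <- -cpp_reconstruct_dilate(-(img + h), -img)
  (rec - img) > h / 2
}

#' Label connected components
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix; 0 is background, components are numbered from 1.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.logical(mask), connectivity %in% c(4, 8))
  cpp_label_components(mask, as.integer(connectivity))
}

#' Otsu threshold
#'
#' @param values numeric vector in any range.
#' @param nbins histogram resolution.
#' @return the threshold maximizing between-class variance.
#' @export
otsu_threshold <- function(values, nbins = 256) {
  values <- values[is.finite(values)]
  r <- range(values)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(nbins, pmax(1L, as.integer(
    (values - r[1]) / diff(r) * nbins) + 1L)), nbins)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(nbins) - 0.5) / nbins * diff(r)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[nbins]
  sigma_b <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  # well-separated modes give a plateau of maximizers; take its midpoint
  best <- which(sigma_b >= max(sigma_b) - 1e-12)
  mids[best[ceiling(length(best) / 2)]]
}

# Gaussian 1-D kernel, normalized
gaussian_kernel <- function(width, sigma) {
  h <- (width - 1) / 2
  x <- seq(-h, h, by = 1)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Separable Gaussian smoothing
#'
#' @param img numeric matrix.
#' @param width odd kernel side (default 5).
#' @param sigma standard deviation in pixels (default 1).
#' @return smoothed matrix (replicate border).
#' @export
gaussian_smooth <- function(img, width = 5, sigma = 1.0) {
  if (width < 1 || width %% 2 == 0) stop("gaussian_smooth: width must be odd")
  if (sigma <= 0) stop("gaussian_smooth: sigma must be > 0")
  cpp_sepconv(img, gaussian_kernel(width, sigma))
}
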