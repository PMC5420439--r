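#' Field-of-view mask
#'
#' Fundus photographs show a bright circular aperture on a black surround.
#' The mask is true where the per-pixel maximum over R, G, B exceeds
#' `threshold`; the largest connected component is kept and its holes are
#' filled, yielding a single connected region.
#'
#' @param img a [fundus_image].
#' @param threshold intensity fraction in (0, 1); default 0.06.
#' @param erode_radius optional disc radius by which the final mask is
#'   eroded (default 0). A small erosion (2-3 px) discards the ragged,
#'   near-black aperture rim whose pixels otherwise form sliver superpixels
#'   with meaningless color statistics.
#' @return an object of class `fov_mask`: list with logical `mask` and
#'   integer `area`.
#' @export
compute_fov_mask <- function(img, threshold = 0.06, erode_radius = 0) {
  stopifnot(inherits(img, "fundus_image"))
  if (threshold <= 0 || threshold >= 1)
    stop("compute_fov_mask: threshold must be in (0, 1)")
  mx <- pmax(img$pixels[, , 1], img$pixels[, , 2], img$pixels[, , 3])
  m <- mx > threshold
  if (!any(m))
    stop("compute_fov_mask: degenerate input, no pixel above threshold ",
         threshold)
  lab <- label_components(m, connectivity = 8)
  biggest <- which.max(tabulate(lab[lab > 0]))
  m <- lab == biggest
  m <- fill_holes(m)
  if (erode_radius > 0)
    m <- m_erode(matrix(as.numeric(m), nrow(m)), disc_se(erode_radius)) > 0.5
  if (!any(m))
    stop("compute_fov_mask: erosion emptied the mask")
  structure(list(mask = m, area = sum(m)), class = "fov_mask")
}

# Fill holes: background components not touching the image border are
# interior and get absorbed.
fill_holes <- function(mask) {
  bg <- label_components(!mask, connectivity = 4)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0]
  hole <- bg > 0 & !matrix(bg %in% border, nrow(bg), ncol(bg))
  mask | hole
}

#' Contrast enhancement (CLAHE + Gaussian smoothing)
#'
#' Applies contrast-limited adaptive histogram equalization per RGB channel
#' inside the field of view, then a Gaussian smoothing filter (width 5,
#' sigma 1 by default) to suppress noise. Returns the enhanced color image
#' together with the grayscale planes used downstream: the enhanced green
#' plane, the raw green plane, and the CLAHE green plane before smoothing
#' (input of the multiscale vessel detector).
#'
#' @param img a [fundus_image].
#' @param fov a `fov_mask` from [compute_fov_mask()].
#' @param clahe_clip clip limit as a fraction of the tile pixel count
#'   (default 0.01).
#' @param tile tiles per image side (default 8).
#' @param gaussian_width,gaussian_sigma smoothing kernel parameters.
#' @param nbins histogram resolution for CLAHE.
#' @return an object of class `preprocessed_image` with fields
#'   `rgb_enhanced`, `green_enhanced`, `green_raw`, `clahe_gray`, `fov`.
#' @export
enhance <- function(img, fov, clahe_clip = 0.01, tile = 8,
                    gaussian_width = 5, gaussian_sigma = 1.0, nbins = 256) {
  stopifnot(inherits(img, "fundus_image"), inherits(fov, "fov_mask"))
  if (clahe_clip <= 0) stop("enhance: clahe_clip must be > 0")
  if (tile < 2) stop("enhance: tile must be >= 2")
  H <- img$height; W <- img$width
  clahe_rgb <- array(0, c(H, W, 3L))
  rgb_enh <- array(0, c(H, W, 3L))
  for (k in 1:3) {
    cl <- cpp_clahe(img$pixels[, , k], fov$mask, as.integer(tile),
                    as.integer(tile), clahe_clip, as.integer(nbins))
    clahe_rgb[, , k] <- cl
    sm <- gaussian_smooth(cl, gaussian_width, gaussian_sigma)
    sm[sm < 0] <- 0; sm[sm > 1] <- 1
    rgb_enh[, , k] <- sm
  }
  structure(
    list(rgb_enhanced = rgb_enh,
         green_enhanced = rgb_enh[, , 2],
         green_raw = img$pixels[, , 2],
         clahe_gray = clahe_rgb[, , 2],
         fov = fov),
    class = "preprocessed_image")
}

#' @export
print.preprocessed_image <- function(x, ...) {
  cat(sprintf("<preprocessed_image %d x %d, FOV area %d>\n",
              nrow(x$green_enhanced), ncol(x$green_enhanced), x$fov$area))
  invisible(x)
}
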