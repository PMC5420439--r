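#' Channel configuration
#'
#' Structuring-element sizes for the seven-channel stack. Defaults follow
#' the method's reference geometry (1500-pixel-wide images). For small
#' images (synthetic phantoms) set `scale_se = TRUE` to scale every radius
#' and kernel linearly with the image width relative to `reference_width`.
#'
#' @param asf_radii disc radii of the alternating sequential filter.
#' @param median_kernel side of the background median filter (odd).
#' @param line_length line structuring element length for vessel removal.
#' @param line_angles orientations in degrees; the printed 15..165 step 15
#'   enumerates 11 angles, 0 is added to reach the stated 12.
#' @param close_radius disc radius of the closing channel.
#' @param scale_se scale elements with image width (default off).
#' @param reference_width width at which the defaults apply.
#' @return an object of class `channel_config`.
#' @export
channel_config <- function(asf_radii = c(10, 20, 40), median_kernel = 25,
                           line_length = 9,
                           line_angles = c(0, seq(15, 165, by = 15)),
                           close_radius = 10, scale_se = FALSE,
                           reference_width = 1500) {
  structure(list(asf_radii = asf_radii, median_kernel = median_kernel,
                 line_length = line_length, line_angles = line_angles,
                 close_radius = close_radius, scale_se = scale_se,
                 reference_width = reference_width),
            class = "channel_config")
}

# Resolve a config against an image width: apply linear SE scaling if asked.
# Only the background-scale elements (ASF discs, closing disc) scale with
# the field of view; the median window and line length are matched to the
# absolute pixel size of lesions and vessel calibres, which the synthetic
# phantom reproduces one-to-one, so they stay fixed.
resolve_channel_config <- function(config, width) {
  if (!config$scale_se) return(config)
  s <- width / config$reference_width
  config$asf_radii <- pmax(1, round(config$asf_radii * s))
  config$close_radius <- max(1, round(config$close_radius * s))
  config$scale_se <- FALSE
  config
}

#' Dark-structure enhancement channel (ASF background subtraction)
#'
#' An alternating sequential filter -- closing then opening with disc
#' elements of increasing radius -- estimates the lesion-free background
#' `f_ASF`; subtracting the enhanced green plane and clipping at zero
#' leaves the dark structures (lesions, vessels, fovea) high-valued.
#'
#' @param green_enhanced enhanced green plane in `[0, 1]`.
#' @param radii ascending disc radii (default 10, 20, 40).
#' @return nonnegative matrix `I_dark_enhanced`.
#' @export
channel_dark_enhanced <- function(green_enhanced, radii = c(10, 20, 40)) {
  f <- green_enhanced
  for (r in radii) {
    se <- disc_se(r)
    f <- m_open(m_close(f, se), se)
  }
  pmax(f - green_enhanced, 0)
}

#' Small-lesion channel (shade correction + linear vessel removal)
#'
#' A 25x25 median filter estimates the background `I_bg`. On the
#' dark-structures-positive residue `I_bg - I_green`, twelve openings with
#' length-9 line elements keep elongated (vessel) structure; their pixelwise
#' maximum is subtracted so that only small round dark structures --
#' candidate red lesions -- remain high-valued.
#'
#' @param green_enhanced enhanced green plane.
#' @param median_kernel odd background window side.
#' @param line_length line element length.
#' @param line_angles orientations in degrees.
#' @return nonnegative matrix `I_lesions`.
#' @export
channel_lesions <- function(green_enhanced, median_kernel = 25,
                            line_length = 9,
                            line_angles = c(0, seq(15, 165, by = 15))) {
  I_bg <- median_filter(green_enhanced, median_kernel)
  inv_sc <- I_bg - green_enhanced          # lesions and vessels positive
  vessels <- matrix(-Inf, nrow(inv_sc), ncol(inv_sc))
  for (a in line_angles)
    vessels <- pmax(vessels, m_open(inv_sc, line_se(line_length, a)))
  pmax(inv_sc - vessels, 0)
}

#' Closing channel
#'
#' Grayscale closing with a radius-10 disc; fills dark structures thinner
#' than the element.
#'
#' @param green_enhanced enhanced green plane.
#' @param radius disc radius.
#' @return matrix `I_close` (pixelwise >= input).
#' @export
channel_close <- function(green_enhanced, radius = 10) {
  m_close(green_enhanced, disc_se(radius))
}

#' Hue channel
#'
#' HSV hue of the enhanced RGB image, as hue angle / 360 in `[0, 1)`.
#' Zero-saturation pixels get hue 0.
#'
#' @param rgb_enhanced `H x W x 3` array in `[0, 1]`.
#' @return matrix `I_Hue_enhanced`.
#' @export
channel_hue <- function(rgb_enhanced) {
  d <- dim(rgb_enhanced)
  r <- matrix(rgb_enhanced[, , 1], d[1], d[2])
  g <- matrix(rgb_enhanced[, , 2], d[1], d[2])
  b <- matrix(rgb_enhanced[, , 3], d[1], d[2])
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  h <- matrix(0, nrow(r), ncol(r))
  i <- d > 0 & mx == r
  h[i] <- ((g - b)[i] / d[i]) %% 6
  i <- d > 0 & mx == g & mx != r
  h[i] <- (b - r)[i] / d[i] + 2
  i <- d > 0 & mx == b & mx != r & mx != g
  h[i] <- (r - g)[i] / d[i] + 4
  h / 6
}

#' CMYK magenta channel
#'
#' `K = 1 - max(R,G,B)`, `M = (1 - G - K) / (1 - K)`, with `M = 0` where
#' `K = 1` (pure black). Dark reddish structures appear bright.
#'
#' @param rgb_enhanced `H x W x 3` array in `[0, 1]`.
#' @return matrix `I_M` in `[0, 1]`.
#' @export
channel_m_cmyk <- function(rgb_enhanced) {
  d <- dim(rgb_enhanced)
  r <- matrix(rgb_enhanced[, , 1], d[1], d[2])
  g <- matrix(rgb_enhanced[, , 2], d[1], d[2])
  b <- matrix(rgb_enhanced[, , 3], d[1], d[2])
  K <- 1 - pmax(r, g, b)
  M <- matrix(0, nrow(r), ncol(r))
  ok <- K < 1
  M[ok] <- (1 - g - K)[ok] / (1 - K)[ok]
  pmin(pmax(M, 0), 1)
}

#' Build the seven-channel stack
#'
#' Assembles, in frozen order: raw green `I_G`, enhanced green `I_green`,
#' ASF dark-enhancement `I_dark_enhanced`, small-lesion channel
#' `I_lesions`, closing `I_close`, hue `I_Hue_enhanced`, and CMYK magenta
#' `I_M`. Feature indices depend on this order.
#'
#' @param pre a `preprocessed_image`.
#' @param config a [channel_config].
#' @return an object of class `channel_stack`: list `channels` of seven
#'   `H x W` matrices with canonical `names`.
#' @export
build_channel_stack <- function(pre, config = channel_config()) {
  stopifnot(inherits(pre, "preprocessed_image"))
  cfg <- resolve_channel_config(config, ncol(pre$green_enhanced))
  ch <- list(
    I_G = pre$green_raw,
    I_green = pre$green_enhanced,
    I_dark_enhanced = channel_dark_enhanced(pre$green_enhanced,
                                            cfg$asf_radii),
    I_lesions = channel_lesions(pre$green_enhanced, cfg$median_kernel,
                                cfg$line_length, cfg$line_angles),
    I_close = channel_close(pre$green_enhanced, cfg$close_radius),
    I_Hue_enhanced = channel_hue(pre$rgb_enhanced),
    I_M = channel_m_cmyk(pre$rgb_enhanced))
  d <- dim(ch[[1]])
  for (nm in names(ch))
    if (!identical(dim(ch[[nm]]), d))
      stop("build_channel_stack: internal shape mismatch in ", nm)
  structure(list(channels = ch, names = names(ch), config = cfg),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  cat("<channel_stack: ", paste(x$names, collapse = ", "), ">\n", sep = "")
  invisible(x)
}
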