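#' Single-scale morphological vessel map
#'
#' Five-step vessel segmentation on the (unsmoothed) CLAHE green plane:
#' \enumerate{
#'   \item `f1 = closing(opening(I_CLAHE, disc(r)), disc(r))` -- background
#'     estimate at scale `r`;
#'   \item `f2 = max(f1 - I_CLAHE, 0)` -- dark structures become bright;
#'   \item `f3 = sum` of the 12 line openings of `f2` (length 9, angles
#'     0 and 15..165 step 15) -- reinforces elongated structure;
#'   \item `f4` = opening-by-reconstruction of `f3` (marker =
#'     `erosion(f3, disc(marker_radius))`, default radius 1) -- removes
#'     small residues while preserving connected ridges; a radius-2 marker
#'     erases width-3 vessels outright, hence the default;
#'   \item binarize `f4` -- by default at a small quantile of its FOV
#'     values (the response is sparse and highly precise, so the vessel
#'     phase is essentially `f4 > 0`); Otsu and regional-minima-complement
#'     modes are available -- and close with a 3x3 element.
#' }
#'
#' @param clahe_gray CLAHE green plane (before Gaussian smoothing).
#' @param radius disc radius (scale), typically 2..5.
#' @param fov optional `fov_mask`; restricts the threshold estimate.
#' @param line_length,line_angles linear element geometry for step 3.
#' @param step5_mode `"quantile"` (default), `"otsu"` or
#'   `"regional_minima"`.
#' @param quantile_level quantile of the FOV `f4` values used by the
#'   default mode (the mask is `f4 > quantile`); default 0.9.
#' @param marker_radius erosion disc radius of the reconstruction marker.
#' @return logical vessel mask.
#' @export
vessel_map_single_scale <- function(clahe_gray, radius, fov = NULL,
                                    line_length = 9,
                                    line_angles = c(0, seq(15, 165, 15)),
                                    step5_mode = c("quantile", "otsu",
                                                   "regional_minima"),
                                    quantile_level = 0.9,
                                    marker_radius = 1) {
  if (radius < 1) stop("vessel_map_single_scale: radius must be >= 1")
  step5_mode <- match.arg(step5_mode)
  se <- disc_se(radius)
  f1 <- m_close(m_open(clahe_gray, se), se)
  f2 <- pmax(f1 - clahe_gray, 0)
  f3 <- matrix(0, nrow(f2), ncol(f2))
  for (a in line_angles) f3 <- f3 + m_open(f2, line_se(line_length, a))
  f4 <- m_open_reconstruct(f3, disc_se(marker_radius))
  inside <- if (is.null(fov)) rep(TRUE, length(f4)) else fov$mask
  if (step5_mode == "quantile") {
    thr <- stats::quantile(f4[inside], quantile_level, names = FALSE)
    bin <- f4 > thr
  } else if (step5_mode == "otsu") {
    vals <- f4[inside]
    if (max(vals) - min(vals) < 1e-12) {
      bin <- matrix(FALSE, nrow(f4), ncol(f4))
    } else {
      thr <- otsu_threshold(vals)
      bin <- f4 > thr
    }
  } else {
    bin <- !regional_minima(f4)
    bin <- bin & f4 > 0        # the complement alone would flood flat zeros
  }
  if (!is.null(fov)) bin <- bin & fov$mask
  closed <- m_close(matrix(as.numeric(bin), nrow(bin), ncol(bin)),
                    expand.grid(dy = -1:1, dx = -1:1))
  out <- closed > 0.5
  if (!is.null(fov)) out <- out & fov$mask
  out
}

#' Multiscale vessel map (logical-OR fusion)
#'
#' Runs [vessel_map_single_scale()] at each scale and fuses the masks with
#' a pixelwise OR.
#'
#' @inheritParams vessel_map_single_scale
#' @param scales disc radii; default `c(2, 3, 4, 5)`.
#' @return an object of class `vessel_map`: `mask` (the OR fusion) and
#'   `per_scale_masks`.
#' @export
vessel_map_multiscale <- function(clahe_gray, scales = c(2, 3, 4, 5),
                                  fov = NULL, line_length = 9,
                                  line_angles = c(0, seq(15, 165, 15)),
                                  step5_mode = c("quantile", "otsu",
                                                 "regional_minima"),
                                  quantile_level = 0.9) {
  step5_mode <- match.arg(step5_mode)
  per <- lapply(scales, function(r)
    vessel_map_single_scale(clahe_gray, r, fov, line_length, line_angles,
                            step5_mode, quantile_level))
  mask <- Reduce(`|`, per)
  structure(list(mask = mask, per_scale_masks = per, scales = scales),
            class = "vessel_map")
}

#' Remove red-labelled candidates lying on vessels
#'
#' A red candidate whose pixel overlap with the vessel mask strictly
#' exceeds `overlap_frac` of its area is relabelled non-red (red lesions
#' do not occur on vessels).
#'
#' @param cands a `candidate_set`.
#' @param predictions logical vector, `TRUE` = red.
#' @param vessels a `vessel_map` (or logical matrix).
#' @param overlap_frac suppression threshold (default 0.5, strict).
#' @return updated logical predictions.
#' @export
suppress_vessel_candidates <- function(cands, predictions, vessels,
                                       overlap_frac = 0.5) {
  stopifnot(inherits(cands, "candidate_set"))
  vmask <- if (inherits(vessels, "vessel_map")) vessels$mask else vessels
  out <- predictions
  for (i in which(predictions)) {
    ov <- sum(vmask[cands$pixels[[i]]]) / cands$table$area[i]
    if (ov > overlap_frac) out[i] <- FALSE
  }
  out
}

#' Remove red-labelled candidates at the fovea
#'
#' The fovea centre is estimated from the optic disc: displaced from the OD
#' centre toward the image centre by `distance_factor * od_diameter`.
#' Red candidates whose barycentre lies within
#' `radius_factor * od_diameter` of that point are relabelled non-red.
#'
#' @param cands a `candidate_set`.
#' @param predictions logical vector, `TRUE` = red.
#' @param od_center optic disc centre `(row, col)`, 0-based; `NULL` skips
#'   suppression with a warning.
#' @param od_diameter optic disc diameter in pixels.
#' @param distance_factor,radius_factor fovea geometry (defaults 2.5, 1.0).
#' @param image_center optional `(row, col)` override of the displacement
#'   target (defaults to the raster centre).
#' @return updated logical predictions; attribute `fovea_center` records
#'   the estimate, attribute `skipped` flags a missing OD.
#' @export
suppress_fovea <- function(cands, predictions, od_center, od_diameter,
                           distance_factor = 2.5, radius_factor = 1.0,
                           image_center = NULL) {
  stopifnot(inherits(cands, "candidate_set"))
  if (is.null(od_center)) {
    warning("suppress_fovea: no optic disc location; suppression skipped")
    attr(predictions, "skipped") <- TRUE
    return(predictions)
  }
  if (is.null(image_center))
    image_center <- (cands$dim - 1) / 2
  dir <- image_center - od_center
  nrm <- sqrt(sum(dir^2))
  if (nrm == 0) dir <- c(0, 0) else dir <- dir / nrm
  fovea <- od_center + distance_factor * od_diameter * dir
  r <- radius_factor * od_diameter
  d <- sqrt((cands$table$by - fovea[1])^2 + (cands$table$bx - fovea[2])^2)
  out <- predictions & !(d <= r)
  attr(out, "fovea_center") <- fovea
  out
}

#' Locate the optic disc
#'
#' Brightest-region heuristic: the mean-RGB intensity is heavily blurred
#' and its maximum inside an eroded field of view taken as the OD centre
#' (ties broken toward the smallest `(row, col)`). The diameter defaults to
#' one sixth of the FOV diameter.
#'
#' @param pre a `preprocessed_image`.
#' @param fov a `fov_mask`.
#' @param blur_sigma blur scale in pixels (default width / 30).
#' @param diameter_fraction OD diameter as a fraction of the FOV diameter.
#' @return list `center` (0-based `(row, col)`), `diameter`, `confident`.
#' @export
locate_optic_disc <- function(pre, fov = pre$fov, blur_sigma = NULL,
                              diameter_fraction = 1 / 6) {
  intensity <- (pre$rgb_enhanced[, , 1] + pre$rgb_enhanced[, , 2] +
                  pre$rgb_enhanced[, , 3]) / 3
  W <- ncol(intensity)
  if (is.null(blur_sigma)) blur_sigma <- W / 30
  width <- 2 * ceiling(2 * blur_sigma) + 1
  blur <- gaussian_smooth(intensity, width, blur_sigma)
  fov_diam <- 2 * sqrt(fov$area / pi)
  er <- ceiling(fov_diam * diameter_fraction / 4)
  core <- m_erode(matrix(as.numeric(fov$mask), nrow(fov$mask)),
                  disc_se(max(1, er))) > 0.5
  if (!any(core)) core <- fov$mask
  vals <- blur
  vals[!core] <- -Inf
  mx <- max(vals)
  hits <- which(vals == mx, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  center <- as.numeric(hits[1, ]) - 1
  inner_mean <- mean(blur[core])
  list(center = center,
       diameter = fov_diam * diameter_fraction,
       confident = is.finite(mx) && (mx - inner_mean) > 0.02)
}

#' Final lesion map
#'
#' Union of the pixels of all red-labelled candidates.
#'
#' @param cands a `candidate_set`.
#' @param predictions logical vector, `TRUE` = red.
#' @param scores optional per-candidate scores to carry along.
#' @return an object of class `lesion_map`: logical `mask` and
#'   `candidate_scores` for the surviving candidates.
#' @export
final_lesion_map <- function(cands, predictions, scores = NULL) {
  stopifnot(inherits(cands, "candidate_set"))
  H <- cands$dim[1]; W <- cands$dim[2]
  mask <- matrix(FALSE, H, W)
  for (i in which(as.logical(predictions)))
    mask[cands$pixels[[i]]] <- TRUE
  structure(list(mask = mask,
                 candidate_scores = if (is.null(scores)) NULL
                 else scores[as.logical(predictions)]),
            class = "lesion_map")
}
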