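#' Run the front half of the pipeline on one image
#'
#' Preprocess, segment into superpixel candidates, build the channel stack
#' and compute raw features. Returns everything later stages need.
#'
#' @param img a [fundus_image].
#' @param region_size SLIC region size `S`.
#' @param compactness SLIC weight `m`.
#' @param channel_cfg a [channel_config]; pass `scale_se = TRUE` for small
#'   images.
#' @param fov_threshold FOV threshold (see [compute_fov_mask()]).
#' @param fov_erode FOV rim erosion in pixels (default 2): keeps sliver
#'   superpixels of near-black aperture-edge pixels out of the candidate
#'   set.
#' @return list with `pre`, `fov`, `sp`, `cands`, `features` (raw, n x 31).
#' @export
mcmf_process_image <- function(img, region_size = 50, compactness = 10,
                               channel_cfg = channel_config(),
                               fov_threshold = 0.06, fov_erode = 2) {
  fov <- compute_fov_mask(img, fov_threshold, fov_erode)
  pre <- enhance(img, fov)
  sp <- slic_segment(pre, fov, slic_params(region_size, compactness))
  cands <- extract_candidates(sp)
  stack <- build_channel_stack(pre, channel_cfg)
  feats <- compute_features(stack, cands, pre)
  list(pre = pre, fov = fov, sp = sp, cands = cands, features = feats)
}

#' Label candidates against a ground-truth lesion mask
#'
#' A candidate is positive when lesion pixels make up at least `frac_cand`
#' of its area, or when it covers at least `frac_comp` of some ground-truth
#' component (so small lesions inside a large superpixel still mark it).
#'
#' @param cands a `candidate_set`.
#' @param lesion_mask logical ground truth.
#' @param frac_cand,frac_comp thresholds (defaults 0.25 and 0.5).
#' @return logical vector, `TRUE` = red lesion candidate.
#' @export
label_candidates <- function(cands, lesion_mask, frac_cand = 0.25,
                             frac_comp = 0.5) {
  stopifnot(inherits(cands, "candidate_set"))
  gl <- label_components(lesion_mask, 8)
  ng <- max(gl)
  comp_area <- if (ng > 0) tabulate(gl[gl > 0], ng) else integer(0)
  vapply(seq_len(nrow(cands$table)), function(i) {
    ix <- cands$pixels[[i]]
    inles <- sum(lesion_mask[ix])
    if (inles == 0) return(FALSE)
    if (inles / cands$table$area[i] >= frac_cand) return(TRUE)
    comps <- gl[ix]
    comps <- comps[comps > 0]
    tb <- table(comps)
    any(as.integer(tb) / comp_area[as.integer(names(tb))] >= frac_comp)
  }, logical(1))
}

#' Train the red-lesion classifier on labelled feature sets
#'
#' Pools raw per-image feature matrices, fits the z-normalization on the
#' pool, and fits the Fisher discriminant with the red class projecting
#' above the projected-means midpoint threshold.
#'
#' @param feature_list list of raw `n_i x 31` matrices.
#' @param label_list list of logical vectors (`TRUE` = red).
#' @param epsilon ridge for the within-class scatter (see [fit_fda()]).
#' @return an `fda_model` carrying the normalization stats.
#' @export
mcmf_train <- function(feature_list, label_list, epsilon = NULL) {
  X <- do.call(rbind, feature_list)
  y <- unlist(label_list)
  stopifnot(nrow(X) == length(y))
  nf <- normalize_features(X)
  if (sum(y) < 2L || sum(!y) < 2L)
    stop("mcmf_train: need at least 2 samples in each class")
  fit_fda(nf$x[y, , drop = FALSE], nf$x[!y, , drop = FALSE],
          epsilon = epsilon, norm_stats = nf$stats)
}

#' Detect red lesions in one image
#'
#' Scores every candidate with the trained model, thresholds (midpoint `c`
#' by default), then applies the morphological postprocessing: multiscale
#' vessel suppression and fovea-zone suppression around the located optic
#' disc. Returns the final lesion map plus the intermediate decisions, so
#' callers can evaluate the pipeline with and without postprocessing.
#'
#' @param model an `fda_model` with stored `norm_stats`.
#' @param processed output of [mcmf_process_image()].
#' @param c_override optional decision threshold.
#' @param postprocess apply vessel + fovea suppression (default `TRUE`).
#' @param vessel_scales disc radii of the multiscale vessel detector.
#' @param vessel_overlap_frac candidate/vessel overlap above which a red
#'   candidate is suppressed.
#' @param od optional list `(center, diameter)`; located automatically
#'   when `NULL`.
#' @return list with `scores`, `pred_raw` (before postprocessing), `pred`
#'   (after), `lesion_map`, `vessels`, `od`, `suppressed` (logical),
#'   `retained` (label-blind postprocessing survivors, the support of the
#'   image-level score) and `image_score`.
#' @export
mcmf_detect <- function(model, processed, c_override = NULL,
                        postprocess = TRUE, vessel_scales = c(2, 3, 4, 5),
                        vessel_overlap_frac = 0.5, od = NULL) {
  stopifnot(inherits(model, "fda_model"))
  if (is.null(model$norm_stats))
    stop("mcmf_detect: model carries no normalization stats")
  z <- normalize_features(processed$features, model$norm_stats)$x
  scores <- fda_score(model, z)
  pred_raw <- fda_classify(model, z, c_override)
  pred <- pred_raw
  vessels <- NULL
  retained <- rep(TRUE, length(scores))
  if (postprocess) {
    vessels <- vessel_map_multiscale(processed$pre$clahe_gray,
                                     scales = vessel_scales,
                                     fov = processed$fov)
    if (is.null(od)) {
      loc <- locate_optic_disc(processed$pre, processed$fov)
      od <- list(center = loc$center, diameter = loc$diameter,
                 confident = loc$confident)
    }
    # suppressibility of every candidate, label-blind: the image-level
    # score must not be driven by vessel or fovea superpixels
    retained <- suppress_vessel_candidates(processed$cands, retained,
                                           vessels, vessel_overlap_frac)
    retained <- as.logical(suppress_fovea(processed$cands, retained,
                                          od$center, od$diameter))
    pred <- pred_raw & retained
  }
  lm <- final_lesion_map(processed$cands, pred, scores)
  list(scores = scores, pred_raw = pred_raw, pred = as.logical(pred),
       lesion_map = lm, vessels = vessels, od = od,
       suppressed = pred_raw & !as.logical(pred),
       retained = retained,
       image_score = image_score(scores[retained]))
}
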