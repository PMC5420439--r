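#' Specification of a synthetic fundus phantom
#'
#' States the world the generator renders: a circular field of view on a
#' black surround, a reddish background with a smooth illumination
#' gradient, a bright optic disc, a dark fovea placed 2.5 OD diameters
#' from the disc toward the image centre (the anatomical spacing the
#' fovea-suppression step assumes), a dark branching vessel tree, and dark
#' round microaneurysms plus irregular hemorrhage blobs planted off-vessel.
#'
#' @param size `(H, W)` in pixels; default 512 x 512.
#' @param seed integer; generation is fully reproducible per seed.
#' @param n_microaneurysms,n_hemorrhages lesion counts.
#' @param ma_radius_range,hem_radius_range lesion radii in pixels.
#' @param lesion_contrast green-intensity deficit of a lesion relative to
#'   its local background, in (0, 1); default 0.15.
#' @param vessel_widths candidate vessel stem widths in pixels.
#' @param noise_sigma additive Gaussian pixel noise; default 0.02.
#' @param background_gradient relative amplitude of the illumination ramp.
#' @param od_center,od_radius,fovea_center,fovea_radius geometry overrides
#'   (0-based `(row, col)`); defaults are derived from `size`.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(512, 512), seed = 1L,
                         n_microaneurysms = 6, n_hemorrhages = 2,
                         ma_radius_range = c(2, 4),
                         hem_radius_range = c(4, 9),
                         lesion_contrast = 0.15,
                         vessel_widths = 2:6,
                         noise_sigma = 0.02,
                         background_gradient = 0.15,
                         od_center = NULL, od_radius = NULL,
                         fovea_center = NULL, fovea_radius = NULL) {
  if (lesion_contrast <= 0 || lesion_contrast >= 1)
    stop("phantom_spec: lesion_contrast must be in (0, 1)")
  H <- size[1]; W <- size[2]
  ctr <- c((H - 1) / 2, (W - 1) / 2)
  fov_r <- 0.46 * min(H, W)
  if (is.null(od_radius)) od_radius <- 0.165 * fov_r
  if (is.null(od_center)) od_center <- ctr + c(0, -0.8 * fov_r)
  if (is.null(fovea_radius)) fovea_radius <- 0.5 * od_radius
  if (is.null(fovea_center)) {
    dir <- ctr - od_center
    dir <- dir / sqrt(sum(dir^2))
    fovea_center <- od_center + 2.5 * (2 * od_radius) * dir
  }
  geom_ok <- function(p, r) sqrt(sum((p - ctr)^2)) + r <= fov_r + 1e-9
  if (!geom_ok(od_center, 0.9 * od_radius) ||
      !geom_ok(fovea_center, fovea_radius))
    stop("phantom_spec: optic disc / fovea geometry falls outside the FOV")
  structure(list(size = size, seed = as.integer(seed),
                 n_microaneurysms = n_microaneurysms,
                 n_hemorrhages = n_hemorrhages,
                 ma_radius_range = ma_radius_range,
                 hem_radius_range = hem_radius_range,
                 lesion_contrast = lesion_contrast,
                 vessel_widths = vessel_widths,
                 noise_sigma = noise_sigma,
                 background_gradient = background_gradient,
                 fov_center = ctr, fov_radius = fov_r,
                 od_center = od_center, od_radius = od_radius,
                 fovea_center = fovea_center, fovea_radius = fovea_radius),
            class = "phantom_spec")
}

disc_mask <- function(H, W, center, radius) {
  yy <- matrix(0:(H - 1), H, W)
  xx <- matrix(0:(W - 1), H, W, byrow = TRUE)
  (yy - center[1])^2 + (xx - center[2])^2 <= radius^2
}

soft_disc <- function(H, W, center, radius, feather) {
  yy <- matrix(0:(H - 1), H, W)
  xx <- matrix(0:(W - 1), H, W, byrow = TRUE)
  d <- sqrt((yy - center[1])^2 + (xx - center[2])^2)
  w <- (radius + feather - d) / feather
  pmin(pmax(w, 0), 1)
}

# Stamp discs of the given radius along a polyline; returns linear indices.
stamp_path <- function(H, W, ys, xs, radius) {
  off <- disc_se(max(1, radius))
  idx <- integer(0)
  for (t in seq_along(ys)) {
    yy <- round(ys[t]) + off[, 1]
    xx <- round(xs[t]) + off[, 2]
    ok <- yy >= 0 & yy < H & xx >= 0 & xx < W
    idx <- c(idx, yy[ok] + xx[ok] * H + 1L)
  }
  unique(idx)
}

#' Generate a synthetic fundus image with per-pixel ground truth
#'
#' Renders, in order: background with illumination gradient, circular FOV,
#' optic disc, fovea, a branching vessel tree grown from the disc, then the
#' lesions (microaneurysms as discs, hemorrhages as unions of 2-5
#' overlapping discs) at `lesion_contrast` below the local background, and
#' finally Gaussian noise. Truth masks are recorded before noise. Lesions
#' are planted off-vessel, away from the disc and outside the fovea
#' suppression zone, so every planted lesion is a recoverable target.
#'
#' @param spec a [phantom_spec].
#' @return list with `image` (a [fundus_image]) and `truth`: logical masks
#'   `lesion_mask`, `vessel_mask`, `od_mask`, `fovea_mask`, `fov_mask`,
#'   the geometry, and `lesion_components` (center, radius, type).
#' @export
generate_synthetic_fundus <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$size[1]; W <- spec$size[2]
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  yy <- matrix(0:(H - 1), H, W)
  xx <- matrix(0:(W - 1), H, W, byrow = TRUE)
  fov <- disc_mask(H, W, spec$fov_center, spec$fov_radius)

  grad <- 1 + spec$background_gradient *
    ((xx - spec$fov_center[2]) / W + 0.5 * (yy - spec$fov_center[1]) / H)
  base <- list(r = 0.62, g = 0.42, b = 0.16)
  img <- array(0, c(H, W, 3))
  img[, , 1] <- base$r * grad
  img[, , 2] <- base$g * grad
  img[, , 3] <- base$b * grad

  # optic disc: bright, softly feathered
  odw <- soft_disc(H, W, spec$od_center, spec$od_radius, 4)
  img[, , 1] <- img[, , 1] + 0.25 * odw
  img[, , 2] <- img[, , 2] + 0.30 * odw
  img[, , 3] <- img[, , 3] + 0.20 * odw
  od_mask <- disc_mask(H, W, spec$od_center, spec$od_radius)

  # fovea: dark, softly feathered
  fvw <- soft_disc(H, W, spec$fovea_center, spec$fovea_radius, 6)
  img[, , 1] <- img[, , 1] - 0.08 * fvw
  img[, , 2] <- img[, , 2] - 0.10 * fvw
  img[, , 3] <- img[, , 3] - 0.03 * fvw
  fovea_mask <- disc_mask(H, W, spec$fovea_center, spec$fovea_radius)

  # vessel tree: random walks out of the optic disc
  vessel_mask <- matrix(FALSE, H, W)
  n_main <- 6L
  angles <- runif(n_main, 0, 2 * pi)
  for (b in seq_len(n_main)) {
    width <- spec$vessel_widths[sample.int(length(spec$vessel_widths), 1)]
    pos <- spec$od_center
    ang <- angles[b]
    len <- round(1.3 * spec$fov_radius)
    ys <- numeric(0); xs <- numeric(0)
    for (t in seq_len(len)) {
      ang <- ang + rnorm(1, 0, 0.08)
      pos <- pos + 1.5 * c(sin(ang), cos(ang))
      if (sqrt(sum((pos - spec$fov_center)^2)) > spec$fov_radius - 2) break
      ys <- c(ys, pos[1]); xs <- c(xs, pos[2])
    }
    if (!length(ys)) next
    taper <- pmax(1, width * (1 - 0.5 * seq_along(ys) / length(ys)))
    third <- max(1, length(ys) %/% 3)
    segs <- split(seq_along(ys), ceiling(seq_along(ys) / third))
    for (s in segs) {
      wr <- max(1, round(mean(taper[s]) / 2))
      vessel_mask[stamp_path(H, W, ys[s], xs[s], wr)] <- TRUE
    }
    # one child branch halfway, at 60% width
    if (length(ys) > 20) {
      t0 <- length(ys) %/% 2
      cpos <- c(ys[t0], xs[t0]); cang <- ang + sample(c(-1, 1), 1) * 0.8
      cys <- numeric(0); cxs <- numeric(0)
      for (t in seq_len(len %/% 2)) {
        cang <- cang + rnorm(1, 0, 0.1)
        cpos <- cpos + 1.5 * c(sin(cang), cos(cang))
        if (sqrt(sum((cpos - spec$fov_center)^2)) > spec$fov_radius - 2) break
        cys <- c(cys, cpos[1]); cxs <- c(cxs, cpos[2])
      }
      if (length(cys))
        vessel_mask[stamp_path(H, W, cys, cxs,
                               max(1, round(width * 0.6 / 2)))] <- TRUE
    }
  }
  vessel_mask <- vessel_mask & fov
  vdepth <- matrix(0, H, W)
  vdepth[vessel_mask] <- 1
  img[, , 1] <- img[, , 1] - 0.10 * vdepth
  img[, , 2] <- img[, , 2] - 0.16 * vdepth
  img[, , 3] <- img[, , 3] - 0.03 * vdepth

  # lesions: rejection-sampled clear of vessels, disc and fovea zone
  lesion_mask <- matrix(FALSE, H, W)
  lesion_components <- list()
  place_ok <- function(center, radius) {
    if (sqrt(sum((center - spec$fov_center)^2)) >
        0.9 * spec$fov_radius - radius) return(FALSE)
    if (sqrt(sum((center - spec$od_center)^2)) <
        1.3 * spec$od_radius + radius) return(FALSE)
    if (sqrt(sum((center - spec$fovea_center)^2)) <
        1.1 * (2 * spec$od_radius) + radius) return(FALSE)
    r <- radius + 3
    y0 <- max(1, round(center[1]) - r); y1 <- min(H, round(center[1]) + r)
    x0 <- max(1, round(center[2]) - r); x1 <- min(W, round(center[2]) + r)
    # clear of vessels and of already-planted lesions
    !any(vessel_mask[y0:y1, x0:x1]) && !any(lesion_mask[y0:y1, x0:x1])
  }
  sample_center <- function(radius) {
    for (try in 1:200) {
      a <- runif(1, 0, 2 * pi)
      rr <- sqrt(runif(1)) * 0.85 * spec$fov_radius
      ctr <- spec$fov_center + rr * c(sin(a), cos(a))
      if (place_ok(ctr, radius)) return(ctr)
    }
    NULL
  }
  drop_lesion <- function(mask_idx, contrast) {
    depth <- c(0.6, 1, 0.2) * contrast
    for (k in 1:3) {
      p <- img[, , k]
      p[mask_idx] <- p[mask_idx] - depth[k]
      img[, , k] <<- p
    }
    lesion_mask[mask_idx] <<- TRUE
  }
  for (i in seq_len(spec$n_microaneurysms)) {
    rad <- runif(1, spec$ma_radius_range[1], spec$ma_radius_range[2])
    ctr <- sample_center(rad)
    if (is.null(ctr)) next
    m <- which(disc_mask(H, W, ctr, rad))
    drop_lesion(m, spec$lesion_contrast)
    lesion_components[[length(lesion_components) + 1L]] <-
      list(center = ctr, radius = rad, type = "microaneurysm")
  }
  for (i in seq_len(spec$n_hemorrhages)) {
    rad <- runif(1, spec$hem_radius_range[1], spec$hem_radius_range[2])
    ctr <- sample_center(rad * 1.6)
    if (is.null(ctr)) next
    nb <- sample(2:5, 1)
    m <- logical(H * W)
    for (k in seq_len(nb)) {
      off <- runif(2, -0.6, 0.6) * rad
      m[which(disc_mask(H, W, ctr + off, rad * runif(1, 0.5, 1)))] <- TRUE
    }
    m <- which(m)
    drop_lesion(m, spec$lesion_contrast)
    lesion_components[[length(lesion_components) + 1L]] <-
      list(center = ctr, radius = rad, type = "hemorrhage")
  }

  # black surround, then noise (truth already recorded)
  for (k in 1:3) { p <- img[, , k]; p[!fov] <- 0; img[, , k] <- p }
  if (spec$noise_sigma > 0)
    img <- img + array(rnorm(H * W * 3, 0, spec$noise_sigma), c(H, W, 3))
  img[img < 0] <- 0; img[img > 1] <- 1

  truth <- list(lesion_mask = lesion_mask & fov,
                vessel_mask = vessel_mask,
                od_mask = od_mask, fovea_mask = fovea_mask,
                fov_mask = fov,
                od_center = spec$od_center, od_radius = spec$od_radius,
                fovea_center = spec$fovea_center,
                fovea_radius = spec$fovea_radius,
                lesion_components = lesion_components)
  list(image = fundus_image(img, source_path = NA_character_), truth = truth)
}

#' Generate a labelled synthetic dataset on disk
#'
#' Writes `n_images` phantom images (PNG), their lesion masks (PNG) and a
#' `manifest.csv` with columns `image_id`, `path`, `mask_path`,
#' `n_lesions`, `label`. Every 10-image block contains 3 healthy images
#' (indices 3, 6, 9 mod 10), emulating a screening mix; everything else is
#' drawn from per-image seeds derived from `seed`.
#'
#' @param n_images number of images.
#' @param spec_template a [phantom_spec] supplying all non-seed parameters.
#' @param seed master seed.
#' @param out_dir output directory (created if missing); `NULL` keeps the
#'   dataset in memory only.
#' @return invisibly, a list with `manifest` (data frame) and `phantoms`
#'   (the in-memory image/truth pairs).
#' @export
generate_labeled_dataset <- function(n_images, spec_template = phantom_spec(),
                                     seed = 1L, out_dir = NULL) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  phantoms <- vector("list", n_images)
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    sp <- spec_template
    sp$seed <- as.integer((seed * 1009L + i * 9973L) %% 2147483647L)
    healthy <- (i %% 10L) %in% c(3L, 6L, 9L)
    if (healthy) { sp$n_microaneurysms <- 0L; sp$n_hemorrhages <- 0L }
    ph <- generate_synthetic_fundus(sp)
    phantoms[[i]] <- ph
    n_les <- length(ph$truth$lesion_components)
    img_path <- mask_path <- NA_character_
    if (!is.null(out_dir)) {
      img_path <- file.path(out_dir, sprintf("phantom_%03d.png", i))
      mask_path <- file.path(out_dir, sprintf("phantom_%03d_mask.png", i))
      write_image_png(ph$image$pixels, img_path)
      write_image_png(ph$truth$lesion_mask, mask_path)
    }
    rows[[i]] <- data.frame(image_id = sprintf("phantom_%03d", i),
                            path = img_path, mask_path = mask_path,
                            n_lesions = n_les,
                            label = any(ph$truth$lesion_mask))
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir))
    write.csv(manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
  invisible(list(manifest = manifest, phantoms = phantoms))
}
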