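#' SLIC parameters
#'
#' @param region_size grid interval `S` in pixels (>= 2). For `P` pixels and
#'   `k` initial centres, `S = sqrt(P / k)`; `region_size` is the user-facing
#'   knob and `k` is derived from it.
#' @param compactness weight `m` in the SLIC distance, in `[1, 40]`.
#' @param n_iters assignment/update iterations (early stop when no centre
#'   moves more than 0.5 px).
#' @param enforce_connectivity merge 4-connected fragments after clustering.
#' @param min_region_fraction fragments smaller than this fraction of `S^2`
#'   are absorbed into an adjacent superpixel.
#' @return an object of class `slic_params`.
#' @export
slic_params <- function(region_size, compactness = 10, n_iters = 10,
                        enforce_connectivity = TRUE,
                        min_region_fraction = 0.25) {
  if (region_size < 2) stop("slic_params: region_size must be >= 2")
  if (compactness < 1 || compactness > 40)
    stop("slic_params: compactness must be in [1, 40]")
  if (n_iters < 1) stop("slic_params: n_iters must be >= 1")
  structure(list(region_size = region_size, compactness = compactness,
                 n_iters = n_iters,
                 enforce_connectivity = enforce_connectivity,
                 min_region_fraction = min_region_fraction),
            class = "slic_params")
}

#' sRGB to CIELAB conversion
#'
#' Converts an `H x W x 3` sRGB array (values in `[0, 1]`, D65 white point)
#' to CIELAB, `L` in `[0, 100]`.
#'
#' @param img `H x W x 3` numeric array.
#' @return `H x W x 3` array with planes L, a, b.
#' @export
rgb_to_lab <- function(img) {
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L) stop("rgb_to_lab: need an H x W x 3 array")
  m <- matrix(img, ncol = 3L)
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  array(lab, dim = d)
}

#' SLIC superpixel segmentation
#'
#' Local k-means in the 5-D `[l, a, b, x, y]` space. Cluster centres are
#' initialized on a regular grid of interval `S` inside the field of view,
#' perturbed to the lowest-gradient pixel in a 3x3 neighbourhood; each pixel
#' is assigned to the nearest centre within a `2S x 2S` window under
#' `D = sqrt(d_lab^2 + (m/S)^2 d_xy^2)`; centres are updated to cluster
#' means. Fragments below `min_region_fraction * S^2` are merged into an
#' adjacent superpixel.
#'
#' @param pre a `preprocessed_image` (segmentation runs on `rgb_enhanced`).
#' @param fov a `fov_mask`.
#' @param params a [slic_params].
#' @return an object of class `superpixel_map`: integer `labels` matrix
#'   (`-1` outside the FOV, else `0..N-1`), `n_superpixels`, and the params.
#' @export
slic_segment <- function(pre, fov, params) {
  stopifnot(inherits(pre, "preprocessed_image"), inherits(fov, "fov_mask"),
            inherits(params, "slic_params"))
  S <- params$region_size
  if (fov$area < S^2)
    stop("slic_segment: degenerate input, FOV area (", fov$area,
         ") smaller than one grid cell (", S^2, ")")
  lab3 <- rgb_to_lab(pre$rgb_enhanced)
  L <- lab3[, , 1]; A <- lab3[, , 2]; B <- lab3[, , 3]
  centers <- slic_init_centers(L, A, B, fov$mask, S)
  labels <- NULL
  for (it in seq_len(params$n_iters)) {
    labels <- cpp_slic_assign(L, A, B, centers, S, params$compactness,
                              fov$mask, TRUE)
    newc <- cpp_slic_update(labels, L, A, B, centers)
    shift <- sqrt((newc[, 4] - centers[, 4])^2 + (newc[, 5] - centers[, 5])^2)
    centers <- newc
    if (max(shift) <= 0.5) break
  }
  if (params$enforce_connectivity) {
    min_size <- max(1L, as.integer(round(params$min_region_fraction * S^2)))
    labels <- cpp_enforce_connectivity(labels, min_size)
  } else {
    labels <- relabel_sequential(labels)
  }
  structure(list(labels = labels,
                 n_superpixels = max(labels) + 1L,
                 params = params),
            class = "superpixel_map")
}

# Grid initialization with 3x3 lowest-gradient perturbation.
slic_init_centers <- function(L, A, B, fov, S) {
  H <- nrow(L); W <- ncol(L)
  ys <- as.integer(round(seq(S / 2, H - S / 2, by = S)))
  xs <- as.integer(round(seq(S / 2, W - S / 2, by = S)))
  if (!length(ys)) ys <- as.integer(round(H / 2))
  if (!length(xs)) xs <- as.integer(round(W / 2))
  g <- slic_gradient(L)
  pts <- expand.grid(y = ys, x = xs)
  keep <- fov[cbind(pts$y, pts$x)]
  pts <- pts[keep, , drop = FALSE]
  if (!nrow(pts))
    stop("slic_segment: no grid centre falls inside the FOV")
  centers <- matrix(0, nrow(pts), 5)
  for (i in seq_len(nrow(pts))) {
    y <- pts$y[i]; x <- pts$x[i]
    yy <- pmin(pmax(y + (-1:1), 1L), H)
    xx <- pmin(pmax(x + (-1:1), 1L), W)
    win <- expand.grid(y = unique(yy), x = unique(xx))
    gi <- g[cbind(win$y, win$x)]
    b <- which.min(gi)
    y <- win$y[b]; x <- win$x[b]
    centers[i, ] <- c(L[y, x], A[y, x], B[y, x], y - 1, x - 1)
  }
  centers
}

slic_gradient <- function(L) {
  H <- nrow(L); W <- ncol(L)
  up <- L[c(1, 1:(H - 1)), ]; dn <- L[c(2:H, H), ]
  lf <- L[, c(1, 1:(W - 1))]; rt <- L[, c(2:W, W)]
  (dn - up)^2 + (rt - lf)^2
}

relabel_sequential <- function(labels) {
  u <- sort(unique(labels[labels >= 0]))
  map <- integer(max(u) + 1L)
  map[u + 1L] <- seq_along(u) - 1L
  out <- labels
  inside <- labels >= 0
  out[inside] <- map[labels[inside] + 1L]
  out
}

#' One SLIC assignment step (exposed for verification)
#'
#' Assigns every FOV pixel to its nearest centre under the SLIC distance.
#' With `windowed = TRUE` each centre competes only inside its `2S x 2S`
#' window and unclaimed pixels fall back to the global nearest centre; with
#' `windowed = FALSE` the assignment is the exhaustive argmin over all
#' pixel-centre pairs.
#'
#' @param lab3 `H x W x 3` CIELAB array.
#' @param centers `k x 5` matrix of centres `(l, a, b, y, x)`, 0-based
#'   pixel coordinates.
#' @param S region size; `m` compactness.
#' @param m compactness weight.
#' @param fov logical matrix (default all true).
#' @param windowed see above.
#' @return integer label matrix (0-based, -1 outside `fov`).
#' @export
slic_assign <- function(lab3, centers, S, m, fov = NULL, windowed = TRUE) {
  d <- dim(lab3)
  if (is.null(fov)) fov <- matrix(TRUE, d[1], d[2])
  cpp_slic_assign(lab3[, , 1], lab3[, , 2], lab3[, , 3],
                  centers, S, m, fov, windowed)
}

#' @export
print.superpixel_map <- function(x, ...) {
  cat(sprintf("<superpixel_map %d x %d, %d superpixels, S = %g>\n",
              nrow(x$labels), ncol(x$labels), x$n_superpixels,
              x$params$region_size))
  invisible(x)
}

#' Extract candidates from a superpixel map
#'
#' One candidate per superpixel: pixel set, barycentre (mean of 0-based
#' pixel coordinates), area, and the neighbour set `N(i)` of all candidates
#' whose barycentre lies within `7 * region_size` (ties included).
#'
#' @param sp a `superpixel_map`.
#' @param params the [slic_params] used for segmentation (supplies the
#'   region size for the neighbour radius); defaults to `sp$params`.
#' @param neighbor_factor multiple of the region size defining neighbourhood
#'   (default 7).
#' @return an object of class `candidate_set`: data frame `table` with
#'   columns `id`, `by`, `bx`, `area`; list `pixels` of linear pixel
#'   indices; list `neighbors` of candidate ids; `dim`; `region_size`.
#' @export
extract_candidates <- function(sp, params = sp$params, neighbor_factor = 7) {
  stopifnot(inherits(sp, "superpixel_map"))
  lab <- sp$labels
  H <- nrow(lab); W <- ncol(lab)
  inside <- which(lab >= 0)
  f <- factor(lab[inside], levels = 0:(sp$n_superpixels - 1L))
  pixels <- split(inside, f)
  rows <- ((inside - 1L) %% H)          # 0-based row
  cols <- ((inside - 1L) %/% H)         # 0-based col
  by <- as.numeric(tapply(rows, f, mean))
  bx <- as.numeric(tapply(cols, f, mean))
  area <- as.integer(tabulate(f, nbins = sp$n_superpixels))
  ids <- seq_len(sp$n_superpixels)
  dmat <- as.matrix(stats::dist(cbind(by, bx)))
  radius <- neighbor_factor * params$region_size
  neighbors <- lapply(ids, function(i) {
    j <- as.integer(which(unname(dmat[i, ]) <= radius))
    j[j != i]
  })
  structure(list(
    table = data.frame(id = ids, by = by, bx = bx, area = area),
    pixels = pixels, neighbors = neighbors,
    dim = c(H, W), region_size = params$region_size),
    class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set: %d candidates, median area %g px>\n",
              nrow(x$table), stats::median(x$table$area)))
  invisible(x)
}
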