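# Shared fixtures, built once per test run and cached in this environment.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# A small default phantom (256 px) used by most module tests; the full-size
# 512 px phantom is reserved for the acceptance suite.
small_phantom <- function(seed = 11) {
  fixture(paste0("phantom_", seed), function()
    generate_synthetic_fundus(phantom_spec(size = c(256, 256), seed = seed,
                                           n_microaneurysms = 5,
                                           n_hemorrhages = 1,
                                           hem_radius_range = c(4, 7))))
}

small_preprocessed <- function(seed = 11) {
  fixture(paste0("pre_", seed), function() {
    ph <- small_phantom(seed)
    fov <- compute_fov_mask(ph$image)
    list(phantom = ph, fov = fov, pre = enhance(ph$image, fov))
  })
}

# Naive reference erosion/dilation used as the independent morphology oracle.
naive_morph <- function(img, se, op = c("erode", "dilate")) {
  op <- match.arg(op)
  H <- nrow(img); W <- ncol(img)
  out <- matrix(NA_real_, H, W)
  for (i in 1:H) for (j in 1:W) {
    ii <- i + se[, 1]; jj <- j + se[, 2]
    ok <- ii >= 1 & ii <= H & jj >= 1 & jj <= W
    v <- img[cbind(ii[ok], jj[ok])]
    out[i, j] <- if (op == "erode") min(v) else max(v)
  }
  out
}

digest_sum <- function(x) sum(as.numeric(x) * seq_along(x))

# The 3-candidate contextual-feature toy: mean green (0.2, 0.5, 0.5) on a
# raster whose FOV region is constant 0.5 (so the global mean is exactly
# 0.5), barycentres (0,0), (0,10), (10,0), all mutual neighbours,
# candidate 1 of 4 pixels.
toy_context_acc <- function() {
  green <- matrix(0.5, 32, 32)
  fovm <- matrix(FALSE, 32, 32); fovm[20:29, 20:29] <- TRUE
  px1 <- c(1L, 2L, 33L, 34L)
  green[px1] <- 0.2
  cands <- structure(list(
    table = data.frame(id = 1:3, by = c(0, 0, 10), bx = c(0, 10, 0),
                       area = c(4L, 1L, 1L)),
    pixels = list(px1, 200L, 300L),
    neighbors = list(c(2L, 3L), c(1L, 3L), c(1L, 2L)),
    dim = c(32, 32), region_size = 2),
    class = "candidate_set")
  fov <- structure(list(mask = fovm, area = sum(fovm)), class = "fov_mask")
  list(cands = cands, green = green, fov = fov)
}

disc_mask_test <- function(H, W, center, radius) {
  yy <- matrix(0:(H - 1), H, W)
  xx <- matrix(0:(W - 1), H, W, byrow = TRUE)
  (yy - center[1])^2 + (xx - center[2])^2 <= radius^2
}

expect_matrix_equal <- function(a, b, tol = 1e-12) {
  expect_equal(dim(a), dim(b))
  expect_lt(max(abs(a - b)), tol)
}
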