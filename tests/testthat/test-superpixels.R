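# Build a preprocessed_image wrapper around a raw RGB array so SLIC can be
# exercised on constructed inputs.
make_pre <- function(arr, fov_mask = NULL) {
  H <- dim(arr)[1]; W <- dim(arr)[2]
  if (is.null(fov_mask)) fov_mask <- matrix(TRUE, H, W)
  fov <- structure(list(mask = fov_mask, area = sum(fov_mask)),
                   class = "fov_mask")
  pre <- structure(list(rgb_enhanced = arr, green_enhanced = arr[, , 2],
                        green_raw = arr[, , 2], clahe_gray = arr[, , 2],
                        fov = fov),
                   class = "preprocessed_image")
  list(pre = pre, fov = fov)
}

make_sp <- function(labels, S) {
  structure(list(labels = labels, n_superpixels = max(labels) + 1L,
                 params = slic_params(S)),
            class = "superpixel_map")
}

test_that("rgb_to_lab hits the CIELAB anchors and a reference conversion", {
  arr <- array(0, c(1, 3, 3))
  arr[1, 1, ] <- c(1, 1, 1)      # white
  arr[1, 2, ] <- c(0, 0, 0)      # black
  arr[1, 3, ] <- c(0.5, 0.5, 0.5)
  lab <- rgb_to_lab(arr)
  expect_equal(lab[1, 1, 1], 100, tolerance = 1e-3)
  expect_lt(abs(lab[1, 1, 2]), 0.5)
  expect_lt(abs(lab[1, 1, 3]), 0.5)
  expect_equal(lab[1, 2, ], c(0, 0, 0), tolerance = 1e-6,
               ignore_attr = TRUE)
  # independent sRGB -> XYZ (D65) -> Lab reference for mid-gray
  lin <- ((0.5 + 0.055) / 1.055)^2.4
  Y <- lin                        # gray: Y equals the linear value
  f <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6/29)^2) + 4/29
  L_ref <- 116 * f(Y) - 16
  expect_equal(lab[1, 3, 1], L_ref, tolerance = 1e-3)
  expect_lt(abs(lab[1, 3, 2]), 1e-3)
  expect_lt(abs(lab[1, 3, 3]), 1e-3)
})

test_that("slic_params validates its ranges", {
  expect_error(slic_params(1), "region_size")
  expect_error(slic_params(10, compactness = 0.5), "compactness")
  expect_error(slic_params(10, compactness = 41), "compactness")
  expect_error(slic_params(10, n_iters = 0), "n_iters")
})

test_that("uniform image yields a near-regular grid partition", {
  arr <- array(0.5, c(64, 64, 3))
  mp <- make_pre(arr)
  sp <- slic_segment(mp$pre, mp$fov, slic_params(10))
  expect_gt(sp$n_superpixels, 20)
  areas <- tabulate(sp$labels[sp$labels >= 0] + 1L, sp$n_superpixels)
  expect_true(all(areas >= 0.25 * 100))
  expect_true(all(areas <= 4 * 100))
  # partition property: labels cover exactly the FOV
  expect_equal(sum(areas), 64 * 64)
  expect_false(any(sp$labels < 0))
})

test_that("superpixels adhere to a flat color boundary", {
  arr <- array(0, c(64, 64, 3))
  arr[, 1:32, ] <- 0.25
  arr[, 33:64, 1] <- 0.8; arr[, 33:64, 2] <- 0.6; arr[, 33:64, 3] <- 0.2
  mp <- make_pre(arr)
  sp <- slic_segment(mp$pre, mp$fov, slic_params(16, compactness = 10))
  for (lab in 0:(sp$n_superpixels - 1L)) {
    cols <- which(sp$labels == lab, arr.ind = TRUE)[, 2]
    # a superpixel may not span the boundary by more than 1 px of bleed
    expect_false(min(cols) <= 31 && max(cols) >= 34,
                 label = sprintf("superpixel %d spans the color boundary", lab))
  }
})

test_that("assignment step never increases total within-cluster distance", {
  set.seed(21)
  arr <- array(runif(24 * 24 * 3, 0.3, 0.7), c(24, 24, 3))
  lab3 <- rgb_to_lab(arr)
  S <- 8; m <- 10
  centers <- rbind(c(lab3[6, 6, ], 5, 5), c(lab3[6, 18, ], 5, 17),
                   c(lab3[18, 6, ], 17, 5), c(lab3[18, 18, ], 17, 17))
  dtot <- function(labels, centers) {
    tot <- 0
    for (i in 1:24) for (j in 1:24) {
      k <- labels[i, j] + 1L
      dlab2 <- sum((c(lab3[i, j, ]) - centers[k, 1:3])^2)
      dxy2 <- (i - 1 - centers[k, 4])^2 + (j - 1 - centers[k, 5])^2
      tot <- tot + dlab2 + (m / S)^2 * dxy2
    }
    tot
  }
  # exhaustive (non-windowed) assignment: the k-means argument applies
  labels <- slic_assign(lab3, centers, S, m, windowed = FALSE)
  for (it in 1:4) {
    centers_new <- mcmf:::cpp_slic_update(labels, lab3[, , 1], lab3[, , 2],
                                          lab3[, , 3], centers)
    labels_new <- slic_assign(lab3, centers_new, S, m, windowed = FALSE)
    # with centres fixed, re-assignment can only lower the objective
    expect_lte(dtot(labels_new, centers_new), dtot(labels, centers_new) + 1e-9)
    labels <- labels_new; centers <- centers_new
  }
})

test_that("higher compactness gives more grid-like segmentations", {
  set.seed(33)
  arr <- array(pmin(pmax(0.5 + rnorm(48 * 48 * 3, 0, 0.08), 0), 1),
               c(48, 48, 3))
  mp <- make_pre(arr)
  blen <- function(m) {
    # raw clustering: connectivity enforcement would smooth away exactly
    # the raggedness this property is about
    sp <- slic_segment(mp$pre, mp$fov,
                       slic_params(12, compactness = m,
                                   enforce_connectivity = FALSE))
    l <- sp$labels
    sum(l[-1, ] != l[-nrow(l), ]) + sum(l[, -1] != l[, -ncol(l)])
  }
  expect_lt(blen(40), blen(1))
})

test_that("extract_candidates: neighbour radius, symmetry, trivia", {
  # single label
  sp1 <- make_sp(matrix(0L, 8, 8), 4)
  c1 <- extract_candidates(sp1)
  expect_equal(nrow(c1$table), 1)
  expect_length(c1$neighbors[[1]], 0)
  expect_equal(c1$table$area, 64)

  # two single-pixel candidates at controlled barycentre distances; S = 2
  for (d in c(13, 14, 15)) {           # 7 * S = 14
    lab <- matrix(-1L, 4, 20)
    lab[1, 1] <- 0L; lab[1, 1 + d] <- 1L
    cc <- extract_candidates(make_sp(lab, 2))
    if (d <= 14) {                     # ties at exactly 7S included
      expect_equal(cc$neighbors[[1]], 2)
      expect_equal(cc$neighbors[[2]], 1)
    } else {
      expect_length(cc$neighbors[[1]], 0)
    }
  }

  # random map: symmetry against the all-pairs oracle
  set.seed(4)
  arr <- array(runif(64 * 64 * 3), c(64, 64, 3))
  mp <- make_pre(arr)
  sp <- slic_segment(mp$pre, mp$fov, slic_params(8))
  cc <- extract_candidates(sp)
  n <- nrow(cc$table)
  dm <- as.matrix(stats::dist(cbind(cc$table$by, cc$table$bx)))
  for (i in seq_len(n)) {
    oracle <- setdiff(which(dm[i, ] <= 7 * 8), i)
    expect_equal(sort(cc$neighbors[[i]]), sort(oracle))
    for (j in cc$neighbors[[i]]) expect_true(i %in% cc$neighbors[[j]])
  }
  # barycentre inside bounding box; areas sum to FOV
  for (i in seq_len(n)) {
    rows <- (cc$pixels[[i]] - 1) %% 64
    cols <- (cc$pixels[[i]] - 1) %/% 64
    expect_gte(cc$table$by[i], min(rows)); expect_lte(cc$table$by[i], max(rows))
    expect_gte(cc$table$bx[i], min(cols)); expect_lte(cc$table$bx[i], max(cols))
  }
  expect_equal(sum(cc$table$area), 64 * 64)
})

test_that("slic_segment rejects a FOV smaller than one grid cell", {
  arr <- array(0.5, c(64, 64, 3))
  fovm <- matrix(FALSE, 64, 64); fovm[30:33, 30:33] <- TRUE
  mp <- make_pre(arr, fovm)
  expect_error(slic_segment(mp$pre, mp$fov, slic_params(16)), "degenerate")
})
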