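make_label_sp <- function(labels, S) {
  structure(list(labels = labels, n_superpixels = max(labels) + 1L,
                 params = slic_params(S)),
            class = "superpixel_map")
}

make_stack <- function(channels) {
  structure(list(channels = channels, names = names(channels),
                 config = channel_config()),
            class = "channel_stack")
}

test_that("candidate_channel_stats: hand cases and brute-force oracle", {
  # one 4-pixel candidate with known values in channel 1
  lab <- matrix(-1L, 8, 8)
  lab[1, 1:4] <- 0L
  cands <- extract_candidates(make_label_sp(lab, 2))
  ch1 <- matrix(0, 8, 8); ch1[1, 1:4] <- c(0.1, 0.2, 0.3, 0.4)
  chans <- stats::setNames(rep(list(ch1), 7),
                           c("I_G", "I_green", "I_dark_enhanced", "I_lesions",
                             "I_close", "I_Hue_enhanced", "I_M"))
  st <- make_stack(chans)
  s <- candidate_channel_stats(st, cands)
  expect_equal(dim(s), c(1, 28))
  expect_equal(unname(s[1, 1:4]), c(0.4, 0.1, 0.25, 0.25))

  # single pixel: all four stats equal the value
  lab1 <- matrix(-1L, 4, 4); lab1[2, 2] <- 0L
  c1 <- extract_candidates(make_label_sp(lab1, 2))
  chv <- lapply(1:7, function(k) matrix(k / 10, 4, 4))
  names(chv) <- names(chans)
  s1 <- candidate_channel_stats(make_stack(chv), c1)
  for (k in 1:7) expect_equal(unname(s1[1, (k - 1) * 4 + 1:4]),
                              rep(k / 10, 4))

  # random candidates on a random stack vs a naive per-pixel loop
  set.seed(14)
  labs <- matrix(sample(0:5, 20 * 20, replace = TRUE), 20, 20)
  cr <- extract_candidates(make_label_sp(labs, 4))
  chr <- lapply(1:7, function(k) matrix(runif(400), 20, 20))
  names(chr) <- names(chans)
  sr <- candidate_channel_stats(make_stack(chr), cr)
  for (i in seq_len(nrow(cr$table))) {
    for (k in 1:7) {
      v <- chr[[k]][cr$pixels[[i]]]
      expect_equal(unname(sr[i, (k - 1) * 4 + 1:4]),
                   c(max(v), min(v), mean(v), stats::median(v)),
                   tolerance = 1e-12)
    }
  }
})

test_that("global_stats: closed forms and loop oracle", {
  mk <- function(green, fovm) {
    structure(list(green_enhanced = green,
                   fov = structure(list(mask = fovm, area = sum(fovm)),
                                   class = "fov_mask")),
              class = "preprocessed_image")
  }
  allm <- matrix(TRUE, 10, 10)
  expect_equal(unname(global_stats(mk(matrix(0.5, 10, 10), allm))),
               c(0.5, 0.0))
  half <- matrix(c(rep(0, 50), rep(1, 50)), 10, 10)
  expect_equal(unname(global_stats(mk(half, allm))), c(0.5, 0.5))
  set.seed(6)
  g <- matrix(runif(100), 10, 10)
  fovm <- matrix(runif(100) > 0.3, 10, 10)
  got <- global_stats(mk(g, fovm))
  v <- g[fovm]
  expect_equal(unname(got), c(mean(v), sqrt(mean((v - mean(v))^2))),
               tolerance = 1e-12)
})

# Independent oracle for the contextual feature: direct transcription of the
# formula, one term at a time.
context_oracle <- function(avG, av_global, bary, areas, neighbors,
                           denom = "pixels") {
  n <- length(avG)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in neighbors[[i]]) {
      diff2 <- (avG[i] - avG[j])^2
      d1 <- if (avG[i] <= avG[j]) diff2 else -diff2
      d2 <- sum((bary[i, ] - bary[j, ])^2)
      acc <- acc + (avG[i] / av_global) * d1 / d2
    }
    den <- if (denom == "pixels") areas[i] else max(1, length(neighbors[[i]]))
    if (length(neighbors[[i]])) out[i] <- acc / den
  }
  out
}

# The shared toy candidate set lives in helper-fixtures.R (toy_context_acc).
toy_context <- toy_context_acc

test_that("contextual feature: worked 3-candidate example and oracle", {
  tc <- toy_context()
  s <- contextual_feature(tc$cands, tc$green, tc$fov)
  oracle <- context_oracle(avG = c(0.2, 0.5, 0.5), av_global = 0.5,
                           bary = rbind(c(0, 0), c(0, 10), c(10, 0)),
                           areas = c(4, 1, 1),
                           neighbors = list(c(2, 3), c(1, 3), c(1, 2)))
  expect_equal(s, oracle, tolerance = 1e-12)
  # hand value: (0.2/0.5) * (0.09/100 + 0.09/100) / 4
  expect_equal(s[1], 0.00018, tolerance = 1e-12)
  # darker candidate scores positive; its equal-intensity neighbours, whose
  # only differing neighbour is darker, score negative
  expect_gt(s[1], 0)
  expect_lt(s[2], 0)
  # neighbour-count denominator variant
  s2 <- contextual_feature(tc$cands, tc$green, tc$fov,
                           denominator = "neighbors")
  expect_equal(s2[1], 0.00018 * 4 / 2, tolerance = 1e-12)
})

test_that("contextual feature: no neighbours, sign, degenerate pairs", {
  tc <- toy_context()
  tc$cands$neighbors <- list(integer(0), integer(0), integer(0))
  expect_equal(contextual_feature(tc$cands, tc$green, tc$fov), c(0, 0, 0))
  tc2 <- toy_context()
  tc2$cands$table$by[2] <- 0; tc2$cands$table$bx[2] <- 0  # coincident
  expect_warning(s <- contextual_feature(tc2$cands, tc2$green, tc2$fov),
                 "coincident")
  expect_true(all(is.finite(s)))
})

test_that("contextual feature is translation invariant and scales as 1/len^2", {
  tc <- toy_context()
  s0 <- contextual_feature(tc$cands, tc$green, tc$fov)
  sh <- tc
  sh$cands$table$by <- sh$cands$table$by + 7.5
  sh$cands$table$bx <- sh$cands$table$bx - 3.25
  expect_equal(contextual_feature(sh$cands, sh$green, sh$fov), s0,
               tolerance = 1e-12)
  sc <- tc
  sc$cands$table$by <- sc$cands$table$by * 2
  sc$cands$table$bx <- sc$cands$table$bx * 2
  expect_equal(contextual_feature(sc$cands, sc$green, sc$fov), s0 / 4,
               tolerance = 1e-12)
})

test_that("candidates darker than all neighbours have nonnegative score", {
  sp <- small_preprocessed()
  p <- mcmf_process_image(sp$phantom$image, region_size = 16,
                          channel_cfg = channel_config(scale_se = TRUE))
  avG <- vapply(p$cands$pixels,
                function(ix) mean(p$pre$green_enhanced[ix]), numeric(1))
  s <- p$features[, "S_context"]
  for (i in seq_along(avG)) {
    js <- p$cands$neighbors[[i]]
    if (length(js) && all(avG[i] < avG[js])) expect_gte(s[i], 0)
  }
})

test_that("assemble_features and the CSV round trip", {
  set.seed(3)
  n <- 5
  s28 <- matrix(runif(n * 28), n, 28)
  g2 <- c(0.4, 0.1)
  sc <- runif(n)
  f <- assemble_features(s28, g2, sc)
  expect_equal(dim(f), c(n, 31))
  expect_equal(unname(f[, 29]), rep(0.4, n))
  expect_equal(unname(f[, 31]), sc)
  expect_error(assemble_features(s28[, 1:27], g2, sc), "28")
  expect_error(assemble_features(s28, g2, sc[1:3]), "length")
  td <- withr::local_tempdir()
  path <- file.path(td, "features.csv")
  write_feature_csv(f, path, image_id = "img1", label = FALSE)
  back <- read_feature_csv(path)
  expect_lt(max(abs(back$x - f)), 1e-9)
})

test_that("normalize_features: fit, reuse, and degenerate columns", {
  set.seed(10)
  x <- matrix(rnorm(200 * 31, mean = 3, sd = 2), 200, 31)
  nf <- normalize_features(x)
  expect_lt(max(abs(colMeans(nf$x))), 1e-9)
  expect_lt(max(abs(colMeans(nf$x^2) - 1)), 1e-9)
  xc <- x; xc[, 5] <- 7
  expect_warning(nfc <- normalize_features(xc), "constant")
  expect_true(all(nfc$x[, 5] == 0))
  # new sample with training stats equals the hand formula
  xnew <- matrix(rnorm(31), 1, 31)
  z <- normalize_features(xnew, nf$stats)$x
  expect_equal(drop(z), (drop(xnew) - nf$stats$mu) / nf$stats$sigma,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(normalize_features(xnew[, 1:30, drop = FALSE], nf$stats),
               "mismatch")
  expect_error(normalize_features(x[1, , drop = FALSE]), "2 samples")
})
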