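feature_stat_names <- function() {
  ch <- paste0("ch", 1:7)
  st <- c("max", "min", "mean", "median")
  c(as.vector(t(outer(ch, st, paste, sep = "_"))),
    "global_mean", "global_std", "S_context")
}

#' Per-candidate channel statistics
#'
#' For every candidate and every channel (in stack order) computes the
#' maximum, minimum, mean and median over the candidate's pixels. The
#' median of an even count is the average of the two middle values.
#'
#' @param stack a `channel_stack`.
#' @param cands a `candidate_set`.
#' @return numeric matrix `n x 28`, columns `ch<k>_{max,min,mean,median}`.
#' @export
candidate_channel_stats <- function(stack, cands) {
  stopifnot(inherits(stack, "channel_stack"), inherits(cands, "candidate_set"))
  n <- nrow(cands$table)
  if (any(cands$table$area < 1L))
    stop("candidate_channel_stats: empty candidate")
  out <- matrix(NA_real_, n, 28)
  for (k in seq_along(stack$channels)) {
    v <- stack$channels[[k]]
    cols <- (k - 1L) * 4L + 1:4
    for (i in seq_len(n)) {
      x <- v[cands$pixels[[i]]]
      out[i, cols] <- c(max(x), min(x), mean(x), stats::median(x))
    }
  }
  colnames(out) <- feature_stat_names()[1:28]
  out
}

#' Global image statistics
#'
#' Mean and population standard deviation of the enhanced green plane over
#' the field of view.
#'
#' @param pre a `preprocessed_image`.
#' @param fov a `fov_mask` (defaults to the one stored in `pre`).
#' @return numeric vector `c(global_mean, global_std)`.
#' @export
global_stats <- function(pre, fov = pre$fov) {
  x <- pre$green_enhanced[fov$mask]
  m <- mean(x)
  c(global_mean = m, global_std = sqrt(mean((x - m)^2)))
}

#' Contextual feature
#'
#' For candidate `i` with mean green intensity `avG_i`, barycentre `p_i`
#' and neighbour set `N(i)`:
#' \deqn{S_i = \frac{1}{D_i} \sum_{j \in N(i)}
#'   \frac{avG_i}{av_{green}} \cdot \frac{d_1(i,j)}{d_2(i,j)}}
#' where `d_1 = +(avG_i - avG_j)^2` if `avG_i <= avG_j` (candidate darker
#' than neighbour, lesion-like) and negative otherwise, and
#' `d_2 = ||p_i - p_j||^2`. The denominator `D_i` is the candidate's pixel
#' count (as printed in the source formula) or, optionally, its neighbour
#' count. Candidates with no neighbours score 0; coincident-barycentre
#' pairs are skipped with a warning.
#'
#' @param cands a `candidate_set`.
#' @param green_enhanced raster supplying candidate mean intensities.
#' @param fov a `fov_mask` (for the global mean).
#' @param denominator `"pixels"` (default, as printed) or `"neighbors"`.
#' @return numeric vector of `S_i`, one per candidate.
#' @export
contextual_feature <- function(cands, green_enhanced, fov,
                               denominator = c("pixels", "neighbors")) {
  stopifnot(inherits(cands, "candidate_set"))
  denominator <- match.arg(denominator)
  av_global <- mean(green_enhanced[fov$mask])
  if (!is.finite(av_global) || av_global <= 0)
    stop("contextual_feature: global mean intensity must be > 0")
  n <- nrow(cands$table)
  avG <- vapply(cands$pixels, function(ix) mean(green_enhanced[ix]),
                numeric(1))
  by <- cands$table$by; bx <- cands$table$bx
  S <- numeric(n)
  warned <- FALSE
  for (i in seq_len(n)) {
    js <- cands$neighbors[[i]]
    if (!length(js)) next
    d2 <- (by[i] - by[js])^2 + (bx[i] - bx[js])^2
    bad <- d2 == 0
    if (any(bad)) {
      if (!warned) {
        warning("contextual_feature: coincident barycentres, pair(s) skipped")
        warned <- TRUE
      }
      js <- js[!bad]; d2 <- d2[!bad]
      if (!length(js)) next
    }
    diff2 <- (avG[i] - avG[js])^2
    d1 <- ifelse(avG[i] <= avG[js], diff2, -diff2)
    den <- if (denominator == "pixels") cands$table$area[i] else length(js)
    S[i] <- sum((avG[i] / av_global) * d1 / d2) / den
  }
  S
}

#' Assemble the 31-dimensional feature matrix
#'
#' Fixed concatenation: 28 channel statistics, 2 global statistics
#' (replicated across candidates), 1 contextual feature.
#'
#' @param stats28 `n x 28` matrix from [candidate_channel_stats()].
#' @param global2 length-2 vector from [global_stats()].
#' @param s_context length-`n` vector from [contextual_feature()].
#' @return `n x 31` matrix with canonical column names.
#' @export
assemble_features <- function(stats28, global2, s_context) {
  stats28 <- as.matrix(stats28)
  if (ncol(stats28) != 28L) stop("assemble_features: expected 28 stat columns")
  if (length(global2) != 2L) stop("assemble_features: expected 2 global stats")
  n <- nrow(stats28)
  if (length(s_context) != n)
    stop("assemble_features: contextual feature length mismatch")
  out <- cbind(stats28,
               matrix(rep(as.numeric(global2), each = n), n, 2),
               s_context)
  colnames(out) <- feature_stat_names()
  stopifnot(ncol(out) == 31L)
  out
}

#' Z-normalize features
#'
#' Each of the 31 dimensions is centred and scaled to unit variance
#' (population standard deviation) over the fitted candidate set. At
#' prediction time pass the training `stats` to reuse the learned
#' normalization. Zero-variance dimensions map to 0 with a warning.
#'
#' @param x `n x 31` raw feature matrix.
#' @param stats optional list `(mu, sigma)` from a previous fit.
#' @return list with `x` (normalized matrix) and `stats = list(mu, sigma)`.
#' @export
normalize_features <- function(x, stats = NULL) {
  x <- as.matrix(x)
  if (is.null(stats)) {
    if (nrow(x) < 2L)
      stop("normalize_features: need at least 2 samples to fit stats")
    mu <- colMeans(x)
    sigma <- sqrt(colMeans(sweep(x, 2, mu)^2))
    stats <- list(mu = mu, sigma = sigma)
  } else {
    if (length(stats$mu) != ncol(x))
      stop("normalize_features: dimension mismatch with stored stats")
  }
  sigma <- stats$sigma
  zero <- sigma == 0
  if (any(zero))
    warning("normalize_features: ", sum(zero),
            " constant feature dimension(s) mapped to 0")
  sig <- ifelse(zero, 1, sigma)
  z <- sweep(sweep(x, 2, stats$mu), 2, sig, "/")
  z[, zero] <- 0
  list(x = z, stats = stats)
}

#' Compute the full feature matrix for one image
#'
#' Convenience wrapper: channel statistics + global statistics + contextual
#' feature, assembled in canonical order.
#'
#' @param stack a `channel_stack`.
#' @param cands a `candidate_set`.
#' @param pre the `preprocessed_image`.
#' @param denominator see [contextual_feature()].
#' @return `n x 31` raw feature matrix.
#' @export
compute_features <- function(stack, cands, pre,
                             denominator = c("pixels", "neighbors")) {
  s28 <- candidate_channel_stats(stack, cands)
  g2 <- global_stats(pre)
  sc <- contextual_feature(cands, pre$green_enhanced, pre$fov,
                           denominator = match.arg(denominator))
  assemble_features(s28, g2, sc)
}

#' Write / read a feature table as CSV
#'
#' @param x `n x 31` feature matrix.
#' @param path CSV path.
#' @param candidate_id,image_id,label optional bookkeeping columns.
#' @return (`write`) the path, invisibly; (`read`) a list with the feature
#'   matrix `x` and the bookkeeping columns.
#' @export
write_feature_csv <- function(x, path, candidate_id = seq_len(nrow(x)),
                              image_id = NA, label = NA) {
  df <- data.frame(candidate_id = candidate_id, image_id = image_id,
                   label = label, as.data.frame(x, check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  x <- as.matrix(df[, feature_stat_names(), drop = FALSE])
  list(x = x, candidate_id = df$candidate_id,
       image_id = df$image_id, label = df$label)
}
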